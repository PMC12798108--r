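# Shared fixtures. table2_mu holds the published worked example: membership
# triplets and D values/ranks for an eight-accession pod pepper panel.

table2_mu <- function() {
  m <- rbind(
    P47 = c(1,      1,      1),
    P48 = c(0.6237, 0.8247, 0.3539),
    P52 = c(0.2281, 0.7464, 0.6238),
    P15 = c(0.2986, 0.6150, 0.5660),
    P63 = c(0,      0.6798, 0.3106),
    P39 = c(0.2821, 0.2737, 0.2309),
    P6  = c(0.1977, 0.0625, 0.0454),
    P18 = c(0.1240, 0,      0))
  colnames(m) <- c("mu_RPHt", "mu_RFW", "mu_RDW")
  m
}

table2_d <- function() {
  c(P47 = 1, P48 = 0.6007, P52 = 0.5327, P15 = 0.4932, P63 = 0.3301,
    P39 = 0.2622, P6 = 0.1019, P18 = 0.0413)
}

# tiny tidy trait table: 2 accessions x 1 trait x 2 conditions x 2 replicates
toy_traits <- function() {
  data.frame(
    accession = rep(c("A1", "A2"), each = 4),
    trait = "PHt",
    condition = rep(c("control", "control", "salt", "salt"), 2),
    replicate = rep(1:2, 4),
    value = c(10, 10, 5, 5, 20, 20, 18, 18))
}

# naive quadratic BH definition: adj_i = min over { p_j * m / rank_j : p_j >= p_i }
bh_naive <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    min(1, min(p[p >= p[i]] * m / r[p >= p[i]]))
  }, numeric(1))
}

# exhaustive hypergeometric upper tail by enumerating all size-n subsets
hyper_enum <- function(N, K, n, k) {
  subsets <- combn(N, n)
  hits <- colSums(subsets <= K) # items 1..K are "in the set"
  mean(hits >= k)
}

# brute-force per-pair Pearson r and two-sided t-test p
cor_brute <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(tt, n - 2, lower.tail = FALSE))
}
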