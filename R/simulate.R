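# Synthetic-data module: generates trait trials, per-feature statistic tables
# and abundance matrices with stored ground truth, so every downstream stage
# is testable without external data. All randomness flows through one integer
# seed scoped with withr::with_seed (global RNG state untouched).

#' Simulation configuration
#'
#' Validated parameter object shared by all generators. Defaults mirror the
#' screening design the package targets: a 63-accession panel measured in six
#' biological replicates, four omics comparison groups, and six samples per
#' abundance matrix.
#'
#' @param n_accessions Number of accessions in the trait trial (>= 1).
#' @param replicates Biological replicates per condition (>= 1).
#' @param trait_means Named control-condition means; defaults
#'   `c(PHt = 25, FW = 15, DW = 1.5)` (cm, g, g) — typical pepper seedlings
#'   at the four-leaf stage plus a week.
#' @param tolerance_effect_range Interval in (0, 1] for the latent retained
#'   fraction of growth under salt; default `c(0.1, 1)`.
#' @param noise_sd Relative (log-normal) measurement noise SD, >= 0;
#'   default 0.05.
#' @param n_genes,n_metabolites Feature counts for omics simulations.
#' @param n_samples Samples per abundance matrix (>= 4 for correlations).
#' @param de_fraction Fraction of features with a planted effect, in [0, 1].
#' @param effect_log2fc Planted |log2FC| magnitude (> 0).
#' @param r_target Planted correlation magnitude for linked pairs, in (0, 1].
#' @param n_linked_pairs Number of planted metabolite-gene pairs (>= 0).
#' @param seed Integer seed governing all draws.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 63, replicates = 6,
                       trait_means = c(PHt = 25, FW = 15, DW = 1.5),
                       tolerance_effect_range = c(0.1, 1),
                       noise_sd = 0.05,
                       n_genes = 1000, n_metabolites = 200, n_samples = 6,
                       de_fraction = 0.1, effect_log2fc = 2,
                       r_target = 0.95, n_linked_pairs = 5,
                       seed = 1L) {
  cfg <- list(n_accessions = n_accessions, replicates = replicates,
              trait_means = trait_means,
              tolerance_effect_range = tolerance_effect_range,
              noise_sd = noise_sd, n_genes = n_genes,
              n_metabolites = n_metabolites, n_samples = n_samples,
              de_fraction = de_fraction, effect_log2fc = effect_log2fc,
              r_target = r_target, n_linked_pairs = n_linked_pairs,
              seed = seed)
  count1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v))
      stop("invalid config field '", field, "': must be an integer >= 1")
  }
  for (f in c("n_accessions", "replicates", "n_genes", "n_metabolites",
              "n_samples")) count1(f)
  if (!is.numeric(trait_means) || length(trait_means) < 1 ||
      is.null(names(trait_means)) || any(trait_means <= 0))
    stop("invalid config field 'trait_means': named positive means required")
  r <- tolerance_effect_range
  if (!is.numeric(r) || length(r) != 2 || r[1] > r[2] || r[1] <= 0 || r[2] > 1)
    stop("invalid config field 'tolerance_effect_range': need lo <= hi in (0, 1]")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("invalid config field 'noise_sd': must be >= 0")
  if (!is.numeric(de_fraction) || de_fraction < 0 || de_fraction > 1)
    stop("invalid config field 'de_fraction': must lie in [0, 1]")
  if (!is.numeric(effect_log2fc) || effect_log2fc <= 0)
    stop("invalid config field 'effect_log2fc': must be > 0")
  if (!is.numeric(r_target) || r_target <= 0 || r_target > 1)
    stop("invalid config field 'r_target': must lie in (0, 1]")
  if (!is.numeric(n_linked_pairs) || n_linked_pairs < 0 ||
      n_linked_pairs != round(n_linked_pairs))
    stop("invalid config field 'n_linked_pairs': must be an integer >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("invalid config field 'seed': must be a finite number")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

new_ground_truth <- function(tolerance_rank = NULL, tolerance_factor = NULL,
                             true_de_features = NULL, linked_pairs = NULL) {
  structure(list(tolerance_rank = tolerance_rank,
                 tolerance_factor = tolerance_factor,
                 true_de_features = true_de_features,
                 linked_pairs = linked_pairs),
            class = "ground_truth")
}

#' Simulate a germplasm salt-stress trait trial
#'
#' Each accession i gets a latent tolerance factor `t_i` drawn uniformly from
#' `tolerance_effect_range`: the fraction of control growth retained under
#' salt. Replicate measurements are the condition expectation (control mean,
#' or control mean x `t_i` under salt) times multiplicative log-normal noise
#' with relative SD `noise_sd` (mean 1, so traits stay positive and unbiased).
#' The ground truth records `t_i` and the implied tolerance ranking.
#'
#' @param config A [sim_config()].
#' @return List with `traits` (tidy data.frame
#'   `accession, trait, condition, replicate, value`) and `truth`
#'   (`tolerance_rank`, most to least tolerant, and named `tolerance_factor`).
#' @export
simulate_trait_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_accessions
    ids <- sprintf("P%0*d", nchar(n), seq_len(n))
    t_i <- runif(n, config$tolerance_effect_range[1],
                 config$tolerance_effect_range[2])
    names(t_i) <- ids
    sdlog <- config$noise_sd
    grid <- expand.grid(replicate = seq_len(config$replicates),
                        condition = c("control", "salt"),
                        trait = names(config$trait_means),
                        accession = ids, stringsAsFactors = FALSE)
    expectation <- config$trait_means[grid$trait] *
      ifelse(grid$condition == "salt", t_i[grid$accession], 1)
    noise <- if (sdlog > 0)
      rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, nrow(grid))
    traits <- data.frame(accession = grid$accession, trait = grid$trait,
                         condition = grid$condition,
                         replicate = grid$replicate,
                         value = as.numeric(expectation * noise),
                         stringsAsFactors = FALSE)
    truth <- new_ground_truth(
      tolerance_rank = ids[order(-t_i, ids)],
      tolerance_factor = t_i)
    list(traits = traits, truth = truth)
  })
}

#' Simulate per-feature comparison statistics for screening
#'
#' For each comparison group, a `de_fraction` of genes and of metabolites get
#' a planted effect: `log2FC = sign x effect_log2fc` (sign random), adjusted
#' p concentrated near 0 (Beta(0.2, 100)), and for metabolites VIP >= 1
#' (1 + Exp(1)). Null features get log2FC ~ N(0, 0.25), uniform adjusted p,
#' and VIP ~ U(0, 1.2). Planted feature ids are recorded per group.
#'
#' @param config A [sim_config()].
#' @param group_labels Character vector (>= 1) of comparison-group labels,
#'   e.g. `c("P18S_VS_CK18S", "P18R_VS_CK18R", "P47S_VS_CK47S",
#'   "P47R_VS_CK47R")`.
#' @return List with `stats` (tidy data.frame
#'   `feature, kind, group, log2fc, adj_p, vip`; VIP is NA for genes) and
#'   `truth` (`true_de_features`: named list of planted id sets per group).
#' @export
simulate_feature_stats <- function(config, group_labels) {
  stopifnot(inherits(config, "sim_config"))
  if (length(group_labels) < 1 || !is.character(group_labels))
    stop("at least one group label is required")
  withr::with_seed(config$seed, {
    gene_ids <- sprintf("gene%0*d", nchar(config$n_genes),
                        seq_len(config$n_genes))
    met_ids <- sprintf("met%0*d", nchar(config$n_metabolites),
                       seq_len(config$n_metabolites))
    sim_kind <- function(ids, group, kind) {
      n <- length(ids)
      n_de <- round(config$de_fraction * n)
      de <- sort(sample.int(n, n_de))
      planted <- logical(n); planted[de] <- TRUE
      log2fc <- rnorm(n, 0, 0.25)
      log2fc[planted] <- sample(c(-1, 1), n_de, replace = TRUE) *
        config$effect_log2fc
      adj_p <- runif(n)
      adj_p[planted] <- rbeta(n_de, 0.2, 100)
      vip <- if (kind == "metabolite") {
        v <- runif(n, 0, 1.2)
        v[planted] <- 1 + rexp(n_de)
        v
      } else rep(NA_real_, n)
      list(stats = data.frame(feature = ids, kind = kind, group = group,
                              log2fc = log2fc, adj_p = adj_p, vip = vip,
                              stringsAsFactors = FALSE),
           planted = ids[planted])
    }
    stats <- list(); truth_sets <- list()
    for (g in group_labels) {
      gs <- sim_kind(gene_ids, g, "gene")
      ms <- sim_kind(met_ids, g, "metabolite")
      stats[[g]] <- rbind(gs$stats, ms$stats)
      truth_sets[[g]] <- c(gs$planted, ms$planted)
    }
    list(stats = do.call(rbind, c(stats, list(make.row.names = FALSE))),
         truth = new_ground_truth(true_de_features = truth_sets))
  })
}

#' Simulate gene and metabolite abundance matrices with planted correlations
#'
#' Background features are i.i.d. standard normal across samples (log-scale
#' abundances). Each of `n_linked_pairs` planted pairs shares a latent factor
#' z: the gene profile is z and the metabolite profile is
#' `s(r z + sqrt(1 - r^2) e)` with independent noise e and a random sign s, so
#' the population correlation is `s * r_target` exactly (and the sample
#' correlation is exactly +/-1 when `r_target = 1`).
#'
#' @param config A [sim_config()]; `n_samples` must be >= 4.
#' @return List with `metab` and `genes` (features x samples matrices) and
#'   `truth` (`linked_pairs`: data.frame `metabolite, gene, sign`).
#' @export
simulate_abundance_matrices <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 4)
    stop("n_samples must be >= 4 for correlation analysis")
  if (config$n_linked_pairs > min(config$n_genes, config$n_metabolites))
    stop("n_linked_pairs exceeds available features")
  withr::with_seed(config$seed, {
    ns <- config$n_samples
    samples <- sprintf("S%0*d", nchar(ns), seq_len(ns))
    gene_ids <- sprintf("gene%0*d", nchar(config$n_genes),
                        seq_len(config$n_genes))
    met_ids <- sprintf("met%0*d", nchar(config$n_metabolites),
                       seq_len(config$n_metabolites))
    genes <- matrix(rnorm(config$n_genes * ns), nrow = config$n_genes,
                    dimnames = list(gene_ids, samples))
    metab <- matrix(rnorm(config$n_metabolites * ns),
                    nrow = config$n_metabolites,
                    dimnames = list(met_ids, samples))
    k <- config$n_linked_pairs
    pairs <- NULL
    if (k > 0) {
      pm <- sample(met_ids, k)
      pg <- sample(gene_ids, k)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      r <- config$r_target
      for (i in seq_len(k)) {
        z <- rnorm(ns)
        genes[pg[i], ] <- z
        metab[pm[i], ] <- sgn[i] * (r * z + sqrt(1 - r^2) * rnorm(ns))
      }
      pairs <- data.frame(metabolite = pm, gene = pg,
                          sign = ifelse(sgn > 0, "positive", "negative"),
                          stringsAsFactors = FALSE)
    }
    list(metab = metab, genes = genes,
         truth = new_ground_truth(linked_pairs = pairs))
  })
}
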