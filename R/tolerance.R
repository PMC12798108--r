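# Germplasm salt-tolerance evaluation: relative traits, membership functions,
# composite D value, injury index.

#' Salt tolerance coefficient (relative trait value)
#'
#' Ratio of the mean trait value under salt stress to the control mean, the
#' "salt tolerance coefficient" used for relative plant height (RPHt),
#' relative fresh weight (RFW) and relative dry weight (RDW).
#'
#' @param salt_mean Numeric vector of trait means under salt stress (>= 0).
#' @param control_mean Numeric vector of control trait means (> 0).
#' @return `salt_mean / control_mean`, dimensionless.
#' @examples
#' relative_trait(5, 20) # 0.25
#' @export
relative_trait <- function(salt_mean, control_mean) {
  if (!is.numeric(salt_mean) || !is.numeric(control_mean))
    stop("salt_mean and control_mean must be numeric")
  if (any(!is.finite(control_mean)) || any(control_mean <= 0))
    stop("degenerate control: control_mean must be finite and > 0")
  if (any(!is.finite(salt_mean)) || any(salt_mean < 0))
    stop("salt_mean must be finite and >= 0")
  salt_mean / control_mean
}

#' Salt tolerance index (STI)
#'
#' Salt-treated value divided by control value. Numerically identical to
#' [relative_trait()] but kept as a distinct operation because the index is
#' reported per trait for selected accessions rather than panel-wide.
#'
#' @param salt_value Trait value under salt stress (>= 0).
#' @param control_value Control trait value (> 0).
#' @return The index, dimensionless.
#' @examples
#' salt_tolerance_index(4, 16) # 0.25
#' @export
salt_tolerance_index <- function(salt_value, control_value) {
  relative_trait(salt_value, control_value)
}

#' Membership function scores for one trait
#'
#' Min-max normalisation of one trait's salt tolerance coefficients across the
#' panel: `mu_i = (x_i - min x) / (max x - min x)`. For growth traits a larger
#' coefficient means more tolerant; set `inverse = TRUE` for cost-type traits
#' to use `1 - mu`.
#'
#' If the trait does not vary (max == min) the membership is undefined; all
#' scores are set to `degenerate` (default 0.5) with a warning, so a constant
#' trait neither rewards nor penalises any accession.
#'
#' @param x Numeric vector of per-accession coefficients (length >= 2).
#' @param inverse Use `1 - mu` (trait where smaller is better). Default FALSE.
#' @param degenerate Value assigned to all accessions when the trait is
#'   constant. Default 0.5.
#' @return Numeric vector of memberships in `[0, 1]`, names preserved.
#' @examples
#' membership_scores(c(2, 4, 8)) # 0, 1/3, 1
#' @export
membership_scores <- function(x, inverse = FALSE, degenerate = 0.5) {
  if (!is.numeric(x) || length(x) < 2)
    stop("membership requires >= 2 accessions")
  if (any(!is.finite(x))) stop("coefficients must be finite")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("trait is constant across accessions; membership set to ",
            degenerate)
    mu <- rep(degenerate, length(x))
  } else {
    mu <- (x - rng[1]) / (rng[2] - rng[1])
  }
  if (inverse) mu <- 1 - mu
  names(mu) <- names(x)
  mu
}

#' Composite salt-tolerance evaluation value (D)
#'
#' Weighted mean of per-trait membership scores; with the default equal
#' weights, `D` is the arithmetic mean of the memberships. Accessions are
#' ranked by D descending (rank 1 = most tolerant); ties share the order of
#' their accession identifiers and are flagged.
#'
#' D is returned at full precision; round to 4 decimals for reporting (the
#' convention used throughout, see [format_scores()]).
#'
#' @param mu Numeric matrix of memberships, accessions in rows (rownames used
#'   as accession ids), traits in columns; all values in `[0, 1]`.
#' @param weights Optional non-negative per-trait weights summing to 1; the
#'   default is equal weights.
#' @return A data.frame with columns `accession`, `D`, `rank`, `tied`, sorted
#'   by rank.
#' @examples
#' mu <- rbind(P47 = c(1, 1, 1), P18 = c(0.1240, 0, 0))
#' composite_d(mu)
#' @export
composite_d <- function(mu, weights = NULL) {
  mu <- as.matrix(mu)
  if (!is.numeric(mu)) stop("mu must be numeric")
  if (any(!is.finite(mu)) || any(mu < 0) || any(mu > 1))
    stop("membership values must lie in [0, 1]")
  k <- ncol(mu)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k)
    stop("weights length (", length(weights), ") != number of traits (", k, ")")
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-8) {
    warning("weights do not sum to 1; renormalising")
    weights <- weights / s
  }
  ids <- rownames(mu)
  if (is.null(ids)) ids <- sprintf("A%0*d", nchar(nrow(mu)), seq_len(nrow(mu)))
  d <- as.numeric(mu %*% weights)
  # descending D, ties broken by accession id lexicographic order
  ord <- order(-d, ids)
  out <- data.frame(accession = ids[ord], D = d[ord],
                    rank = seq_along(ord),
                    tied = (duplicated(d[ord]) | duplicated(d[ord], fromLast = TRUE)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Salt injury index from graded damage counts
#'
#' Weighted-grade percentage summarising visible salt damage over a cohort:
#' `100 * sum(grade * count) / (max_grade * total)`. The grading scale is
#' configurable; the default is the common 0-4 scale.
#'
#' @param counts Named numeric vector mapping grade (integer, as name) to
#'   plant count, or an unnamed vector taken as counts for grades
#'   `0:(length-1)`.
#' @param max_grade Maximum grade G of the scale. Defaults to the largest
#'   grade present in `counts` (at least 1).
#' @return Injury index in percent, in `[0, 100]`.
#' @examples
#' salt_injury_index(c(`0` = 5, `2` = 3, `4` = 2)) # 35
#' @export
salt_injury_index <- function(counts, max_grade = NULL) {
  if (length(counts) == 0) stop("empty grade counts")
  if (is.null(names(counts))) names(counts) <- seq_along(counts) - 1
  grades <- suppressWarnings(as.numeric(names(counts)))
  if (any(is.na(grades)) || any(grades < 0) || any(grades != round(grades)))
    stop("grades must be non-negative integers")
  if (!is.numeric(counts) || any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be non-negative numbers")
  total <- sum(counts)
  if (total < 1) stop("total plants must be >= 1")
  if (is.null(max_grade)) max_grade <- max(grades, 1)
  if (max_grade < max(grades))
    stop("max_grade (", max_grade, ") below largest observed grade")
  100 * sum(grades * counts) / (max_grade * total)
}

#' Evaluate a germplasm panel end to end
#'
#' From a tidy trait table (replicate measurements per accession, trait and
#' condition) computes, per trait, the replicate means, salt tolerance
#' coefficients (salt mean / control mean), membership scores across the
#' panel, and the composite D value with ranks.
#'
#' @param traits A data.frame with columns `accession`, `trait`, `condition`
#'   (`"control"` or `"salt"`), `replicate`, `value` (>= 0). Every accession
#'   must have both conditions for every trait.
#' @param weights Optional per-trait weights for [composite_d()] (order =
#'   sorted trait names unless `weights` is named by trait).
#' @param degenerate Passed to [membership_scores()].
#' @return A data.frame, one row per accession, sorted by rank, with the
#'   relative trait values (`R<trait>`), memberships (`mu_R<trait>`), `D`,
#'   `rank` and `tied`.
#' @examples
#' sim <- simulate_trait_trial(sim_config(n_accessions = 5, noise_sd = 0, seed = 1))
#' evaluate_accessions(sim$traits)
#' @export
evaluate_accessions <- function(traits, weights = NULL, degenerate = 0.5) {
  traits <- validate_trait_table(traits)
  trait_names <- sort(unique(traits$trait))
  accs <- sort(unique(traits$accession))
  # replicate means per (accession, trait, condition)
  m <- aggregate(value ~ accession + trait + condition, data = traits,
                 FUN = mean)
  rel <- matrix(NA_real_, nrow = length(accs), ncol = length(trait_names),
                dimnames = list(accs, trait_names))
  for (tr in trait_names) {
    for (a in accs) {
      ctl <- m$value[m$accession == a & m$trait == tr & m$condition == "control"]
      slt <- m$value[m$accession == a & m$trait == tr & m$condition == "salt"]
      if (length(ctl) != 1 || length(slt) != 1)
        stop("accession '", a, "' is missing a condition for trait '", tr, "'")
      rel[a, tr] <- relative_trait(slt, ctl)
    }
  }
  mu <- apply(rel, 2, membership_scores, degenerate = degenerate)
  rownames(mu) <- accs
  if (!is.null(weights) && !is.null(names(weights)))
    weights <- weights[trait_names]
  d <- composite_d(mu, weights)
  idx <- match(d$accession, accs)
  out <- data.frame(accession = d$accession,
                    rel[idx, , drop = FALSE],
                    mu[idx, , drop = FALSE],
                    D = d$D, rank = d$rank, tied = d$tied,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("accession", paste0("R", trait_names),
                  paste0("mu_R", trait_names), "D", "rank", "tied")
  out
}

#' Round a score table for reporting
#'
#' Rounds membership and D columns to the conventional 4 decimals, leaving
#' identifiers and ranks untouched.
#'
#' @param scores Output of [evaluate_accessions()] or [composite_d()].
#' @param digits Decimal places (default 4).
#' @return The rounded data.frame.
#' @export
format_scores <- function(scores, digits = 4) {
  num <- vapply(scores, is.numeric, logical(1)) & !(names(scores) %in% c("rank"))
  scores[num] <- lapply(scores[num], round, digits = digits)
  scores
}

validate_trait_table <- function(traits) {
  need <- c("accession", "trait", "condition", "replicate", "value")
  if (!is.data.frame(traits) || !all(need %in% names(traits)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  traits$accession <- as.character(traits$accession)
  traits$trait <- as.character(traits$trait)
  traits$condition <- as.character(traits$condition)
  bad <- setdiff(unique(traits$condition), c("control", "salt"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(traits$value) || any(!is.finite(traits$value)) ||
      any(traits$value < 0))
    stop("trait values must be finite and non-negative")
  traits
}
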