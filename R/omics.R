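# Threshold screening of per-feature statistic tables, multi-set overlaps,
# and generic hypergeometric enrichment with BH-FDR.

validate_stats <- function(stats, require_vip = FALSE) {
  need <- c("feature", "log2fc", "adj_p")
  if (!is.data.frame(stats) || !all(need %in% names(stats)))
    stop("stats must have columns: ", paste(need, collapse = ", "))
  if (nrow(stats) == 0) return(stats)
  bad <- !is.finite(stats$log2fc) | !is.finite(stats$adj_p) |
    stats$adj_p < 0 | stats$adj_p > 1
  if (require_vip) {
    if (!"vip" %in% names(stats))
      stop("metabolite screening requires a 'vip' column")
    bad <- bad | !is.finite(stats$vip) | stats$vip < 0
  }
  if (any(bad))
    stop("malformed statistic rows for feature(s): ",
         paste(head(stats$feature[bad], 10), collapse = ", "))
  if (anyDuplicated(stats$feature))
    stop("duplicated feature ids: ",
         paste(head(unique(stats$feature[duplicated(stats$feature)]), 10),
               collapse = ", "))
  stats
}

#' Screen differentially expressed genes
#'
#' Applies the DEG thresholds as printed: significant when
#' `adj_p < p_max` (strict) and `|log2FC| >= fc_min` (inclusive). Up- and
#' down-regulated sets are disjoint by construction.
#'
#' @param stats Data.frame with columns `feature`, `log2fc`, `adj_p` (and
#'   optionally `kind`, which must then be `"gene"` throughout).
#' @param fc_min Minimum absolute log2 fold change, default 1 (inclusive).
#' @param p_max Adjusted-p cutoff, default 0.05 (strict).
#' @return List with character vectors `up` and `down` (sorted feature ids).
#' @examples
#' s <- data.frame(feature = c("g1", "g2", "g3", "g4"),
#'                 log2fc = c(2, -1, 0.5, 3), adj_p = c(0.01, 0.04, 0.001, 0.2))
#' screen_degs(s) # up g1, down g2
#' @export
screen_degs <- function(stats, fc_min = 1, p_max = 0.05) {
  if ("kind" %in% names(stats) && nrow(stats) > 0 &&
      !all(stats$kind == "gene"))
    stop("screen_degs expects gene rows only; found: ",
         paste(setdiff(unique(stats$kind), "gene"), collapse = ", "))
  stats <- validate_stats(stats)
  sig <- stats$adj_p < p_max
  list(up = sort(as.character(stats$feature[sig & stats$log2fc >= fc_min])),
       down = sort(as.character(stats$feature[sig & stats$log2fc <= -fc_min])))
}

#' Screen differentially accumulated metabolites
#'
#' DAM thresholds as printed: `VIP >= vip_min` (inclusive), `adj_p < p_max`
#' (strict) and `|log2FC| >= fc_min` (inclusive), all three jointly.
#'
#' @param stats Data.frame with columns `feature`, `log2fc`, `adj_p`, `vip`
#'   (and optionally `kind`, which must then be `"metabolite"` throughout).
#' @param vip_min Minimum OPLS-DA VIP score, default 1 (inclusive).
#' @inheritParams screen_degs
#' @return List with character vectors `up` and `down`.
#' @export
screen_dams <- function(stats, vip_min = 1, fc_min = 1, p_max = 0.05) {
  if ("kind" %in% names(stats) && nrow(stats) > 0 &&
      !all(stats$kind == "metabolite"))
    stop("screen_dams expects metabolite rows only; found: ",
         paste(setdiff(unique(stats$kind), "metabolite"), collapse = ", "))
  stats <- validate_stats(stats, require_vip = TRUE)
  sig <- stats$adj_p < p_max & stats$vip >= vip_min
  list(up = sort(as.character(stats$feature[sig & stats$log2fc >= fc_min])),
       down = sort(as.character(stats$feature[sig & stats$log2fc <= -fc_min])))
}

#' Exclusive region counts of a multi-set (Venn) overlap
#'
#' For k named sets, counts every one of the `2^k - 1` exclusive membership
#' regions (elements in exactly that combination of sets and no other). The
#' region counts sum to the size of the union; the region containing all sets
#' is the "common" overlap reported in Venn analyses.
#'
#' @param sets Named list of >= 2 vectors (coerced to character sets).
#' @return Data.frame with one row per region: logical membership columns (one
#'   per set), a `region` key like `"A&B"`, and `count`.
#' @examples
#' multiway_overlap(list(A = 1:3, B = 2:3, C = 3:4, D = 3))
#' @export
multiway_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    stop("overlap requires >= 2 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  k <- length(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(grid) <- names(sets)
  counts <- apply(grid, 1, function(g) {
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1, function(row) all(row == g)))
  })
  region <- apply(grid, 1, function(g) paste(names(sets)[as.logical(g)],
                                             collapse = "&"))
  out <- data.frame(grid, region = region, count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Hypergeometric enrichment of a feature selection in annotation sets
#'
#' For each annotation set of size K in a background of size N, with a
#' selection of size n overlapping the set in k features, computes the
#' upper-tail hypergeometric p-value `P(X >= k)` and adjusts across sets with
#' Benjamini-Hochberg.
#'
#' @param selected Character vector of selected features (must be a subset of
#'   the background).
#' @param annotation Named list of non-empty feature sets (e.g. pathways),
#'   each a subset of the background.
#' @param background Character vector of all assayable features. Defaults to
#'   the union of the annotation sets and the selection.
#' @return Data.frame `set_id, set_size, selected_size, overlap, p, fdr`,
#'   sorted by p then set id.
#' @examples
#' hypergeometric_enrichment(letters[1:4],
#'   list(S = letters[1:5]), background = letters[1:10])
#' @export
hypergeometric_enrichment <- function(selected, annotation, background = NULL) {
  if (!is.list(annotation) || length(annotation) == 0 ||
      is.null(names(annotation)))
    stop("annotation must be a non-empty named list of sets")
  annotation <- lapply(annotation, function(s) unique(as.character(s)))
  if (any(lengths(annotation) == 0)) stop("annotation sets must be non-empty")
  selected <- unique(as.character(selected))
  if (is.null(background))
    background <- unique(c(unlist(annotation), selected))
  background <- unique(as.character(background))
  stray <- setdiff(selected, background)
  if (length(stray))
    stop("selected features outside background: ",
         paste(head(stray, 10), collapse = ", "))
  stray <- setdiff(unlist(annotation), background)
  if (length(stray))
    stop("annotated features outside background: ",
         paste(head(stray, 10), collapse = ", "))
  n_bg <- length(background)
  n_sel <- length(selected)
  rows <- lapply(names(annotation), function(id) {
    set <- annotation[[id]]
    K <- length(set)
    k <- length(intersect(selected, set))
    p <- phyper(k - 1, K, n_bg - K, n_sel, lower.tail = FALSE)
    data.frame(set_id = id, set_size = K, selected_size = n_sel,
               overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$set_id), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: sort p ascending, multiply by m/rank, enforce monotonicity from
#' the largest down, cap at 1. Order-preserving; adjusted values are never
#' below the raw p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the original order.
#' @examples
#' bh_adjust(c(0.005, 0.05)) # 0.01, 0.05
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}
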