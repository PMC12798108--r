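# Metabolite-gene co-regulation network: pairwise Pearson correlation with
# t-distribution p-values, BH-FDR edge thresholding, degree ranking, and
# Gephi-compatible export (edge-list CSV and GEXF 1.2).

#' All metabolite x gene Pearson correlations
#'
#' Computes the Pearson correlation R and its two-sided p-value (t statistic
#' with n - 2 degrees of freedom) for every metabolite-gene pair, from two
#' abundance matrices with identical, identically ordered sample columns.
#' Features with zero variance are skipped with a warning (their correlation
#' is undefined).
#'
#' @param metab Numeric matrix, metabolites x samples, rownames = ids.
#' @param genes Numeric matrix, genes x samples, same colnames in the same
#'   order as `metab`; >= 4 samples.
#' @return Data.frame `metabolite, gene, r, p`, metabolites varying slowest.
#' @examples
#' m <- rbind(m1 = 1:6); g <- rbind(g1 = 2 * (1:6))
#' colnames(m) <- colnames(g) <- paste0("s", 1:6)
#' pairwise_correlation(m, g) # r = 1
#' @export
pairwise_correlation <- function(metab, genes) {
  metab <- as.matrix(metab)
  genes <- as.matrix(genes)
  if (is.null(rownames(metab)) || is.null(rownames(genes)))
    stop("abundance matrices need feature ids as rownames")
  if (ncol(metab) != ncol(genes) ||
      !identical(colnames(metab), colnames(genes)))
    stop("sample columns must be identical and identically ordered")
  n <- ncol(metab)
  if (n < 4) stop("correlation requires >= 4 samples (got ", n, ")")
  if (anyNA(metab) || anyNA(genes))
    stop("abundance matrices must not contain missing values; drop or ",
         "pre-filter incomplete features")
  keep_m <- apply(metab, 1, function(x) var_gt0(x))
  keep_g <- apply(genes, 1, function(x) var_gt0(x))
  if (!all(keep_m) || !all(keep_g)) {
    warning("zero-variance feature(s) skipped: ",
            paste(head(c(rownames(metab)[!keep_m], rownames(genes)[!keep_g]),
                       10), collapse = ", "))
    metab <- metab[keep_m, , drop = FALSE]
    genes <- genes[keep_g, , drop = FALSE]
  }
  if (nrow(metab) == 0 || nrow(genes) == 0)
    return(data.frame(metabolite = character(0), gene = character(0),
                      r = numeric(0), p = numeric(0)))
  R <- cor(t(metab), t(genes))
  df <- n - 2
  r2 <- pmin(R^2, 1)
  tt <- abs(R) * sqrt(df / pmax(1 - r2, 0))
  P <- 2 * pt(tt, df, lower.tail = FALSE)
  P[r2 >= 1] <- 0
  out <- data.frame(
    metabolite = rep(rownames(metab), times = ncol(R)),
    gene = rep(colnames(R), each = nrow(R)),
    r = as.numeric(R), p = as.numeric(P), stringsAsFactors = FALSE)
  out <- out[order(match(out$metabolite, rownames(metab)),
                   match(out$gene, rownames(genes))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

var_gt0 <- function(x) {
  r <- range(x)
  is.finite(r[1]) && r[1] != r[2]
}

#' Build the thresholded co-regulation network
#'
#' Adjusts the pairwise p-values with Benjamini-Hochberg across all tested
#' pairs (the whole table is the family), then keeps edges with `|R| > r_min`
#' and `fdr < fdr_max` (both strict, as printed). Edge weight is `|R|`; edge
#' sign is positive iff R > 0. Nodes are the endpoints of kept edges, so the
#' graph is bipartite by construction.
#'
#' @param pairs Output of [pairwise_correlation()].
#' @param r_min Minimum absolute correlation, default 0.8 (strict >).
#' @param fdr_max FDR cutoff, default 0.05 (strict <).
#' @return A `coreg_network`: list with `nodes` (`id`, `kind`) and `edges`
#'   (`metabolite, gene, r, p, fdr, sign, weight`).
#' @export
build_network <- function(pairs, r_min = 0.8, fdr_max = 0.05) {
  need <- c("metabolite", "gene", "r", "p")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  if (nrow(pairs) == 0) return(empty_network())
  if (anyDuplicated(pairs[c("metabolite", "gene")]))
    stop("duplicate metabolite-gene pairs in input")
  pairs$fdr <- bh_adjust(pairs$p)
  keep <- abs(pairs$r) > r_min & pairs$fdr < fdr_max
  e <- pairs[keep, , drop = FALSE]
  if (nrow(e) == 0) return(empty_network())
  e$sign <- ifelse(e$r > 0, "positive", "negative")
  e$weight <- abs(e$r)
  e <- e[order(e$metabolite, e$gene), c("metabolite", "gene", "r", "p",
                                        "fdr", "sign", "weight")]
  rownames(e) <- NULL
  nodes <- data.frame(
    id = c(sort(unique(e$metabolite)), sort(unique(e$gene))),
    kind = c(rep("metabolite", length(unique(e$metabolite))),
             rep("gene", length(unique(e$gene)))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = e), class = "coreg_network")
}

empty_network <- function() {
  structure(list(
    nodes = data.frame(id = character(0), kind = character(0)),
    edges = data.frame(metabolite = character(0), gene = character(0),
                       r = numeric(0), p = numeric(0), fdr = numeric(0),
                       sign = character(0), weight = numeric(0))),
    class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat("coreg_network:", sum(x$nodes$kind == "metabolite"), "metabolites,",
      sum(x$nodes$kind == "gene"), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Degree-centrality ranking of network nodes
#'
#' Connectivity (incident edge count) per node, split into positive and
#' negative edges, sorted by degree descending with ties broken by node id.
#'
#' @param net A `coreg_network` from [build_network()].
#' @return Data.frame `node, kind, degree, positive, negative`, sorted.
#' @export
degree_ranking <- function(net) {
  stopifnot(inherits(net, "coreg_network"))
  if (nrow(net$nodes) == 0)
    return(data.frame(node = character(0), kind = character(0),
                      degree = integer(0), positive = integer(0),
                      negative = integer(0)))
  ends <- c(net$edges$metabolite, net$edges$gene)
  signs <- rep(net$edges$sign, 2)
  deg <- function(ids, want = NULL) {
    sel <- if (is.null(want)) rep(TRUE, length(ends)) else signs == want
    vapply(ids, function(i) sum(ends[sel] == i), integer(1))
  }
  out <- data.frame(node = net$nodes$id, kind = net$nodes$kind,
                    degree = deg(net$nodes$id),
                    positive = deg(net$nodes$id, "positive"),
                    negative = deg(net$nodes$id, "negative"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Export a co-regulation network
#'
#' Writes either a Gephi-ingestible edge list
#' (`source,target,weight,sign,r,p,fdr` CSV) or GEXF 1.2 with typed nodes
#' (kind attribute), weighted undirected edges and sign/r/p/fdr edge
#' attributes. Numbers are serialised with 17 significant digits so that
#' export -> [import_network()] -> export round-trips byte-identically.
#'
#' @param net A `coreg_network`.
#' @param path Output file path.
#' @param format `"edgelist"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edgelist", "gexf")) {
  stopifnot(inherits(net, "coreg_network"))
  format <- match.arg(format)
  e <- net$edges
  if (format == "edgelist") {
    lines <- c("source,target,weight,sign,r,p,fdr",
               if (nrow(e)) paste(e$metabolite, e$gene, fmt_num(e$weight),
                                  e$sign, fmt_num(e$r), fmt_num(e$p),
                                  fmt_num(e$fdr), sep = ","))
    writeLines(lines, path)
  } else {
    doc <- xml2::xml_new_root("gexf",
                              xmlns = "http://www.gexf.net/1.2draft",
                              version = "1.2")
    graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
    natt <- xml2::xml_add_child(graph, "attributes", class = "node")
    xml2::xml_add_child(natt, "attribute", id = "kind", title = "kind",
                        type = "string")
    eatt <- xml2::xml_add_child(graph, "attributes", class = "edge")
    for (a in c("sign", "r", "p", "fdr"))
      xml2::xml_add_child(eatt, "attribute", id = a, title = a,
                          type = if (a == "sign") "string" else "double")
    nodes <- xml2::xml_add_child(graph, "nodes")
    for (i in seq_len(nrow(net$nodes))) {
      nd <- xml2::xml_add_child(nodes, "node", id = net$nodes$id[i],
                                label = net$nodes$id[i])
      av <- xml2::xml_add_child(nd, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "kind",
                          value = net$nodes$kind[i])
    }
    edges <- xml2::xml_add_child(graph, "edges")
    for (i in seq_len(nrow(e))) {
      ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                                source = e$metabolite[i], target = e$gene[i],
                                weight = fmt_num(e$weight[i]))
      av <- xml2::xml_add_child(ed, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "sign", value = e$sign[i])
      for (a in c("r", "p", "fdr"))
        xml2::xml_add_child(av, "attvalue", `for` = a,
                            value = fmt_num(e[[a]][i]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Import a co-regulation network written by [export_network()]
#'
#' @param path File written by [export_network()].
#' @param format `"edgelist"` or `"gexf"`.
#' @return A `coreg_network`.
#' @export
import_network <- function(path, format = c("edgelist", "gexf")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    d <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(source = "character", target = "character",
                                 weight = "numeric", sign = "character",
                                 r = "numeric", p = "numeric",
                                 fdr = "numeric"))
    if (nrow(d) == 0) return(empty_network())
    pairs <- data.frame(metabolite = d$source, gene = d$target, r = d$r,
                        p = d$p, fdr = d$fdr, sign = d$sign,
                        weight = d$weight, stringsAsFactors = FALSE)
  } else {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    enodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
    if (length(enodes) == 0) return(empty_network())
    attv <- function(node, key) {
      xml2::xml_attr(xml2::xml_find_first(
        node, sprintf(".//g:attvalue[@for='%s']", key), ns), "value")
    }
    pairs <- data.frame(
      metabolite = xml2::xml_attr(enodes, "source"),
      gene = xml2::xml_attr(enodes, "target"),
      r = as.numeric(vapply(enodes, attv, "", key = "r")),
      p = as.numeric(vapply(enodes, attv, "", key = "p")),
      fdr = as.numeric(vapply(enodes, attv, "", key = "fdr")),
      sign = vapply(enodes, attv, "", key = "sign"),
      weight = as.numeric(xml2::xml_attr(enodes, "weight")),
      stringsAsFactors = FALSE)
  }
  e <- pairs[order(pairs$metabolite, pairs$gene), , drop = FALSE]
  rownames(e) <- NULL
  nodes <- data.frame(
    id = c(sort(unique(e$metabolite)), sort(unique(e$gene))),
    kind = c(rep("metabolite", length(unique(e$metabolite))),
             rep("gene", length(unique(e$gene)))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = e), class = "coreg_network")
}
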