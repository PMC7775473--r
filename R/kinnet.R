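#' Detect clonal groups from pairwise IBD
#'
#' Builds the graph of pairs with pi-hat above the clonal threshold.
#' A connected component is accepted as a clonal group when *every*
#' within-component pair exceeds the threshold; otherwise the component
#' is split by complete-linkage agglomeration on distance 1 - pi-hat,
#' cut so that every within-group pair still satisfies the rule. One
#' deterministic representative (lexicographically smallest id) is
#' retained per group; the remaining members form the removal set.
#'
#' @param estimates IBD table from [estimate_ibd()].
#' @param threshold pi-hat above which a pair is treated as clonal
#'   (default 0.90).
#' @param ids Optional full node set; samples without a clonal edge form
#'   singleton groups. Defaults to ids present in `estimates`.
#' @return List with `groups` (list of id vectors, multi-member first),
#'   `representatives` (one id per group), `removed` (all
#'   non-representative members) and `assignment`
#'   (`data.frame(id, group, representative)`).
#' @export
clonal_groups <- function(estimates, threshold = 0.90, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(estimates$id1, estimates$id2)))
  e <- estimates[estimates$pi_hat > threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("id1", "id2")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  groups <- list()
  for (ci in seq_len(comp$no)) {
    members <- sort(names(comp$membership)[comp$membership == ci])
    if (length(members) <= 2L) { groups <- c(groups, list(members)); next }
    pm <- matrix(0, length(members), length(members),
                 dimnames = list(members, members))
    pairs <- t(utils::combn(members, 2))
    ph <- pair_pi_hat(estimates, pairs[, 1], pairs[, 2])
    ph[is.na(ph)] <- 0
    pm[pairs] <- ph; pm[pairs[, 2:1, drop = FALSE]] <- ph
    if (all(pm[upper.tri(pm)] > threshold)) {
      groups <- c(groups, list(members))
    } else {
      hc <- stats::hclust(stats::as.dist(1 - pm), method = "complete")
      cl <- stats::cutree(hc, h = (1 - threshold) * (1 - 1e-9))
      groups <- c(groups, unname(split(members, cl)))
    }
  }
  groups <- lapply(groups, sort)
  sizes <- lengths(groups)
  groups <- groups[order(-sizes, vapply(groups, `[`, "", 1L))]
  reps <- vapply(groups, `[`, "", 1L)
  assignment <- data.frame(
    id = unlist(groups),
    group = rep(seq_along(groups), lengths(groups)),
    representative = rep(reps, lengths(groups)),
    stringsAsFactors = FALSE)
  list(groups = groups, representatives = reps,
       removed = setdiff(assignment$id, reps), assignment = assignment)
}

#' Calibrate the first-degree pi-hat range from known pairs
#'
#' Collects pi-hat for known parent-offspring pairs, drops low outliers
#' (presumed mislabelled accessions) and returns the \[min, max\] of the
#' survivors as the interval within which a pair is called first-degree.
#'
#' @param known_pairs `data.frame` with columns `id1`, `id2`.
#' @param estimates IBD table from [estimate_ibd()].
#' @param drop_rule `"iqr"` (default: drop values below
#'   lower quartile - 1.5 IQR) or `"count"` (drop the `drop_n` lowest,
#'   the fixed-count replication mode).
#' @param drop_n Number of lowest values to drop under `"count"`.
#' @return List of class `first_degree_range`: `lower`, `upper`,
#'   `calibration_pairs` (retained values), `dropped` (excluded values),
#'   `rule`.
#' @export
calibrate_first_degree <- function(known_pairs, estimates,
                                   drop_rule = c("iqr", "count"),
                                   drop_n = 2) {
  drop_rule <- match.arg(drop_rule)
  vals <- pair_pi_hat(estimates, as.character(known_pairs$id1),
                      as.character(known_pairs$id2))
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " known pair(s) absent from estimates, ignored")
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) < 3) stop("calibration error: need >=3 known pairs")
  if (drop_rule == "iqr") {
    q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
    lo_cut <- q[1] - 1.5 * (q[2] - q[1])
    keep <- vals >= lo_cut
  } else {
    keep <- !seq_along(vals) %in% order(vals)[seq_len(min(drop_n,
                                                          length(vals)))]
  }
  if (!any(keep)) stop("calibration error: all known pairs dropped")
  structure(list(lower = min(vals[keep]), upper = max(vals[keep]),
                 calibration_pairs = vals[keep], dropped = vals[!keep],
                 rule = drop_rule),
            class = "first_degree_range")
}

#' Build the first-degree relationship network
#'
#' Pairs whose pi-hat falls inside the calibrated range become typed
#' `first_degree` edges (parent-offspring, full siblings and equivalent
#' relationships are indistinguishable from genotype moments alone).
#' Connected components and per-node degree counts are reported; an
#' optional focal-id subnetwork keeps only edges touching the focal set.
#'
#' @param estimates IBD table from [estimate_ibd()] (clonal
#'   representatives only; collapse clones first).
#' @param range A `first_degree_range` from [calibrate_first_degree()],
#'   or a numeric `c(lower, upper)`.
#' @param ids Optional full node set (defaults to ids in `estimates`).
#' @param focal Optional focal sample ids for the subnetwork.
#' @return List with `edges` (`data.frame(id1, id2, type, pi_hat)`),
#'   `components` (named membership vector), `degree` (named integer
#'   vector, first-degree edges per node) and `subnetwork` (edge
#'   `data.frame`, or `NULL` when no `focal` given).
#' @export
relationship_network <- function(estimates, range, ids = NULL, focal = NULL) {
  if (inherits(range, "first_degree_range")) {
    lo <- range$lower; hi <- range$upper
  } else {
    lo <- range[1]; hi <- range[2]
  }
  stopifnot(lo <= hi)
  if (is.null(ids)) ids <- sort(unique(c(estimates$id1, estimates$id2)))
  sel <- estimates$pi_hat >= lo & estimates$pi_hat <= hi &
    estimates$id1 %in% ids & estimates$id2 %in% ids
  edges <- data.frame(id1 = estimates$id1[sel], id2 = estimates$id2[sel],
                      type = "first_degree",
                      pi_hat = estimates$pi_hat[sel],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("id1", "id2")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  sub <- NULL
  if (!is.null(focal)) {
    missing_focal <- setdiff(focal, ids)
    if (length(missing_focal)) {
      warning("focal ids absent, skipped: ",
              paste(missing_focal, collapse = ", "))
      focal <- setdiff(focal, missing_focal)
    }
    sub <- edges[edges$id1 %in% focal | edges$id2 %in% focal, , drop = FALSE]
    attr(sub, "focal") <- focal
  }
  list(edges = edges, components = comp, degree = deg, subnetwork = sub)
}

#' Write a relationship network edge list
#'
#' @param network Output of [relationship_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
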