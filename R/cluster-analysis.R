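#' Build the disease-by-age instance-count matrix
#'
#' Evidence linked to inferred age ranges is excluded. Every remaining
#' instance increments the count of each of its (non-redundant, by default)
#' disease terms at every integer age covered by its range; fractional
#' bounds are rounded outward to the enclosing integers. The per-disease
#' instance totals used for normalisation count distinct instances, not
#' cells.
#'
#' @param store An `apk_store`.
#' @param include_redundant Let redundant hits contribute diseases.
#' @return Object of class `disease_age_matrix`: `diseases`, `ages` (0:120),
#'   `counts` (diseases x 121 integer matrix), `instance_totals`,
#'   `normalized` (`NULL` until [normalize_matrix()]).
#' @export
build_matrix <- function(store, include_redundant = FALSE) {
  stopifnot(inherits(store, "apk_store"))
  if (!nrow(store)) stop("evidence store is empty", call. = FALSE)
  use <- store[!store$inferred, , drop = FALSE]
  if (!nrow(use)) {
    stop("no non-inferred instances in store; nothing to count",
         call. = FALSE)
  }
  inst_terms <- lapply(use$hits, instance_terms,
                       include_redundant = include_redundant)
  diseases <- sort(unique(unlist(inst_terms)))
  if (!length(diseases)) {
    stop("no instances carry ontology disease terms", call. = FALSE)
  }
  ages <- 0:MAX_AGE
  counts <- matrix(0L, nrow = length(diseases), ncol = length(ages),
                   dimnames = list(diseases, ages))
  totals <- stats::setNames(integer(length(diseases)), diseases)
  for (i in seq_len(nrow(use))) {
    terms <- inst_terms[[i]]
    if (!length(terms)) next
    a <- max(0L, floor(use$low_years[i])):min(MAX_AGE, ceiling(use$high_years[i]))
    for (d in terms) {
      counts[d, a + 1L] <- counts[d, a + 1L] + 1L
      totals[d] <- totals[d] + 1L
    }
  }
  structure(list(diseases = diseases, ages = ages, counts = counts,
                 instance_totals = totals, normalized = NULL),
            class = "disease_age_matrix")
}

#' @export
print.disease_age_matrix <- function(x, ...) {
  cat("<disease_age_matrix>", length(x$diseases), "disease(s) x ages 0-120;",
      sum(x$counts), "cell counts;",
      if (is.null(x$normalized)) "not normalised" else "normalised", "\n")
  invisible(x)
}

#' Normalise the matrix for literature-coverage bias
#'
#' Divides each disease-age count by the number of instances associated with
#' that disease, so heavily studied diseases do not dominate. Note that rows
#' of multi-age instances sum to more than 1: each instance contributes one
#' unit per covered age. `row_sum = TRUE` divides by the row sum instead.
#' Diseases with no instances are dropped.
#'
#' @param m A `disease_age_matrix`.
#' @param row_sum Normalise by row sum rather than instance count.
#' @return `m` with `normalized` set.
#' @export
normalize_matrix <- function(m, row_sum = FALSE) {
  stopifnot(inherits(m, "disease_age_matrix"))
  keep <- m$instance_totals > 0L
  m$diseases <- m$diseases[keep]
  m$counts <- m$counts[keep, , drop = FALSE]
  m$instance_totals <- m$instance_totals[keep]
  denom <- if (row_sum) rowSums(m$counts) else m$instance_totals
  m$normalized <- m$counts / denom
  m
}

#' Cluster diseases by their literature age profiles
#'
#' Agglomerative hierarchical clustering of normalised disease rows with
#' distance 1 - Pearson correlation. Diseases with fewer than
#' `min_instances` instances, and rows with zero variance (correlation
#' undefined), are excluded.
#'
#' @param m A `disease_age_matrix` (normalised automatically if needed).
#' @param min_instances Minimum instances per retained disease.
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return List of class `disease_clustering`: `hclust` (a [stats::hclust]
#'   tree), `dist` (the distance matrix), `diseases` (retained leaves).
#' @export
cluster_diseases <- function(m, min_instances = 5L,
                             linkage = c("average", "complete", "single")) {
  stopifnot(inherits(m, "disease_age_matrix"))
  linkage <- match.arg(linkage)
  if (is.null(m$normalized)) m <- normalize_matrix(m)
  keep <- m$instance_totals >= min_instances
  rows <- m$normalized[keep, , drop = FALSE]
  vars <- apply(rows, 1, stats::var)
  rows <- rows[vars > 0, , drop = FALSE]
  if (nrow(rows) < 2L) {
    stop("fewer than 2 usable disease rows after filtering (min_instances = ",
         min_instances, ", zero-variance rows excluded)", call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(rows)))
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, dist = d, diseases = rownames(rows)),
            class = "disease_clustering")
}

#' @export
print.disease_clustering <- function(x, ...) {
  cat("<disease_clustering>", length(x$diseases),
      "disease(s),", x$hclust$method, "linkage, 1 - Pearson distance\n")
  invisible(x)
}

#' Export a disease dendrogram as Newick
#'
#' @param clustering A `disease_clustering`.
#' @param path Output path; when `NULL` the Newick string is returned.
#' @return Newick string, invisibly when written to file.
#' @export
write_dendrogram <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "disease_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(path)) {
    return(ape::write.tree(phy))
  }
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut a disease clustering into k groups
#'
#' @param clustering A `disease_clustering`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k) {
  stopifnot(inherits(clustering, "disease_clustering"))
  stats::cutree(clustering$hclust, k = k)
}

#' Age profile of a disease cluster
#'
#' The profile at each age is the mean instance count over the cluster's
#' diseases; the peak is the earliest age attaining the maximum.
#'
#' @param m A `disease_age_matrix`.
#' @param diseases Character vector of cluster member term IDs.
#' @return List: `profile` (named numeric over ages 0-120), `peak_age`.
#' @export
cluster_age_profile <- function(m, diseases) {
  stopifnot(inherits(m, "disease_age_matrix"), length(diseases) >= 1L)
  missing <- setdiff(diseases, m$diseases)
  if (length(missing)) {
    stop("disease(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  profile <- colMeans(m$counts[diseases, , drop = FALSE])
  names(profile) <- m$ages
  list(profile = profile, peak_age = m$ages[which.max(profile)])
}
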