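#' Cohort phenotype table
#'
#' Holds individually listed cases (one row per individual with tri-state
#' phenotype calls) together with aggregated literature counts for cases
#' not individually listed.  Tri-state calls are coded `1` (affected),
#' `0` (unaffected), `NA` (not assessed).
#'
#' @param individuals data.frame; metadata columns among `id`, `sex`, `age`,
#'   `protein_variant`, `inheritance`, plus one `1/0/NA` column per
#'   phenotype feature.
#' @param aggregates data.frame with columns `feature`, `affected`,
#'   `assessed` (may be empty); `0 <= affected <= assessed` must hold.
#' @return A list of class `cohort_table` with elements `individuals`,
#'   `aggregates` and `features` (the feature column names).
#' @export
cohort_table <- function(individuals,
                         aggregates = data.frame(feature = character(),
                                                 affected = integer(),
                                                 assessed = integer())) {
  meta <- c("id", "sex", "age", "protein_variant", "inheritance")
  features <- setdiff(names(individuals), meta)
  for (f in features) {
    v <- individuals[[f]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop("feature column '", f, "' must be coded 1/0/NA")
    }
  }
  stopifnot(all(c("feature", "affected", "assessed") %in% names(aggregates)))
  if (any(aggregates$affected < 0) ||
      any(aggregates$affected > aggregates$assessed)) {
    stop("aggregates must satisfy 0 <= affected <= assessed")
  }
  structure(list(individuals = individuals, aggregates = aggregates,
                 features = features),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$individuals), "listed individual(s),",
      nrow(x$aggregates), "literature aggregate(s),",
      length(x$features), "feature(s)\n")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' @param individuals_csv path to the per-individual CSV (feature columns
#'   coded 1/0/NA).
#' @param aggregates_csv optional path to the literature-aggregate CSV
#'   (columns `feature`, `affected`, `assessed`).
#' @return A [cohort_table()].
#' @export
read_cohort <- function(individuals_csv, aggregates_csv = NULL) {
  ind <- utils::read.csv(individuals_csv, stringsAsFactors = FALSE)
  agg <- if (is.null(aggregates_csv)) {
    data.frame(feature = character(), affected = integer(),
               assessed = integer())
  } else {
    utils::read.csv(aggregates_csv, stringsAsFactors = FALSE)
  }
  cohort_table(ind, agg)
}

#' Pooled frequency of a phenotype feature
#'
#' Pools affected/assessed counts over the individually listed cases
#' (not-assessed calls excluded) and the literature aggregates for the
#' feature.  The percentage is rounded half-up to an integer, matching the
#' convention of printed clinical tables; it is `NA` (undefined) when
#' nobody was assessed.
#'
#' @param cohort a [cohort_table()].
#' @param feature feature name (a feature column or an aggregate row).
#' @return List with `feature`, `affected`, `assessed`, `percent`.
#' @export
feature_frequency <- function(cohort, feature) {
  stopifnot(inherits(cohort, "cohort_table"))
  in_ind <- feature %in% cohort$features
  in_agg <- feature %in% cohort$aggregates$feature
  if (!in_ind && !in_agg) stop("unknown feature: ", feature)
  affected <- 0L; assessed <- 0L
  if (in_ind) {
    v <- cohort$individuals[[feature]]
    affected <- affected + sum(v == 1, na.rm = TRUE)
    assessed <- assessed + sum(!is.na(v))
  }
  if (in_agg) {
    rows <- cohort$aggregates[cohort$aggregates$feature == feature, ]
    affected <- affected + sum(rows$affected)
    assessed <- assessed + sum(rows$assessed)
  }
  percent <- if (assessed == 0) NA_real_ else
    round_half_up(100 * affected / assessed)
  list(feature = feature, affected = as.integer(affected),
       assessed = as.integer(assessed), percent = percent)
}

#' Frequency table over all features
#'
#' @param cohort a [cohort_table()].
#' @return data.frame with one row per feature (`feature`, `affected`,
#'   `assessed`, `percent`), in decreasing percentage order.
#' @export
frequency_table <- function(cohort) {
  feats <- unique(c(cohort$features, cohort$aggregates$feature))
  rows <- lapply(feats, function(f) as.data.frame(feature_frequency(cohort, f)))
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$percent), -1, out$percent), out$feature), ]
  rownames(out) <- NULL
  out
}

#' Variant hotspot-cluster rule
#'
#' Residue ranges of the two mutational hotspots of the FAM111B protein:
#' cluster 1 upstream of the catalytic region and cluster 2 overlapping the
#' D-box degron.  The default cluster-1 upper bound is 434 (not the 430/431
#' variously printed) so that Tyr434, reported in the upstream hotspot,
#' classifies as cluster 1; both ranges are user-configurable.
#'
#' @param cluster1 integer range `c(lo, hi)` (default `c(416, 434)`).
#' @param cluster2 integer range `c(lo, hi)` (default `c(621, 628)`).
#' @return A list of class `cluster_rule`.
#' @export
cluster_rule <- function(cluster1 = c(416, 434), cluster2 = c(621, 628)) {
  stopifnot(length(cluster1) == 2, length(cluster2) == 2,
            cluster1[1] <= cluster1[2], cluster2[1] <= cluster2[2])
  if (max(cluster1[1], cluster2[1]) <= min(cluster1[2], cluster2[2])) {
    stop("cluster ranges must be disjoint")
  }
  structure(list(cluster1 = as.integer(cluster1),
                 cluster2 = as.integer(cluster2)),
            class = "cluster_rule")
}

#' Assign protein variants to hotspot clusters
#'
#' Parses HGVS p. missense (`p.(Arg627Gly)`) or in-frame deletion
#' (`p.(Lys421del)`) notation, extracts the residue number and tests it
#' against the rule's ranges.
#'
#' @param protein_variant character vector of HGVS p. strings (parentheses
#'   optional).
#' @param rule a [cluster_rule()].
#' @return Character vector with values `"cluster1"`, `"cluster2"` or
#'   `"unclassified"`.
#' @export
assign_cluster <- function(protein_variant, rule = cluster_rule()) {
  stopifnot(inherits(rule, "cluster_rule"))
  pat <- "^p\\.\\(?([A-Z][a-z]{2})([0-9]+)(del|[A-Z][a-z]{2})\\)?$"
  vapply(as.character(protein_variant), function(v) {
    if (is.na(v) || !grepl(pat, v)) {
      stop("unparseable HGVS p. variant: '", v, "'")
    }
    res <- as.integer(sub(pat, "\\2", v))
    if (res >= rule$cluster1[1] && res <= rule$cluster1[2]) "cluster1"
    else if (res >= rule$cluster2[1] && res <= rule$cluster2[2]) "cluster2"
    else "unclassified"
  }, character(1), USE.NAMES = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: conditioning on
#' the margins, the p-value is the sum of hypergeometric probabilities of
#' all tables whose point probability does not exceed that of the observed
#' table times `1 + 1e-7` (the relative tolerance guards floating-point
#' ties).
#'
#' @param table 2x2 matrix (or something coercible) of non-negative integer
#'   counts with grand total >= 1.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  tb <- matrix(as.numeric(table), 2, 2)
  if (any(is.na(tb)) || any(tb < 0) || any(tb != round(tb))) {
    stop("counts must be non-negative integers")
  }
  if (sum(tb) < 1) stop("grand total must be >= 1")
  a <- tb[1, 1]
  m <- tb[1, 1] + tb[2, 1]  # column 1 total
  n <- tb[1, 2] + tb[2, 2]  # column 2 total
  k <- tb[1, 1] + tb[1, 2]  # row 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Genotype-phenotype contrasts between hotspot clusters
#'
#' For each feature, cross-tabulates affected/unaffected against
#' cluster 1/cluster 2 membership of the individually listed cases
#' (not-assessed calls and unclassified variants excluded) and applies
#' [fisher_2x2()].  Unadjusted p-values are reported, as customary for
#' small rare-disease cohorts.
#'
#' @param cohort a [cohort_table()] whose individuals carry
#'   `protein_variant` strings.
#' @param features features to test (default: all).
#' @param rule a [cluster_rule()].
#' @return data.frame with columns `feature`, `affected_c1`, `assessed_c1`,
#'   `affected_c2`, `assessed_c2`, `p_value`.
#' @export
cluster_phenotype_tests <- function(cohort, features = cohort$features,
                                    rule = cluster_rule()) {
  stopifnot(inherits(cohort, "cohort_table"))
  ind <- cohort$individuals
  if (!"protein_variant" %in% names(ind)) {
    stop("individuals lack a 'protein_variant' column")
  }
  has_var <- !is.na(ind$protein_variant) & nzchar(ind$protein_variant)
  cl <- rep(NA_character_, nrow(ind))
  cl[has_var] <- assign_cluster(ind$protein_variant[has_var], rule)
  rows <- lapply(features, function(f) {
    v <- ind[[f]]
    use <- !is.na(v) & cl %in% c("cluster1", "cluster2")
    a1 <- sum(v[use] == 1 & cl[use] == "cluster1")
    n1 <- sum(use & cl == "cluster1")
    a2 <- sum(v[use] == 1 & cl[use] == "cluster2")
    n2 <- sum(use & cl == "cluster2")
    p <- if (n1 + n2 == 0) NA_real_ else
      fisher_2x2(matrix(c(a1, n1 - a1, a2, n2 - a2), 2, byrow = TRUE))
    data.frame(feature = f, affected_c1 = a1, assessed_c1 = n1,
               affected_c2 = a2, assessed_c2 = n2, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
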