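#' Interferon score panel
#'
#' Gene panel and calibrator for relative quantification and the type I
#' interferon score.  The default six interferon-stimulated genes (ISGs)
#' and four housekeeping genes follow the Rice-style signature used for
#' qPCR screening of type I interferonopathies.
#'
#' @param isgs character vector of ISG symbols (default IFIT1, IFI27,
#'   IFI44, IFI44L, ISG15, MX1).
#' @param housekeeping character vector of reference genes (default GAPDH,
#'   HPRT, PPIA, RPL13A); must be disjoint from `isgs`.
#' @param calibrator sample id of the single healthy-donor calibrator.
#' @return A list of class `score_panel`.
#' @export
score_panel <- function(isgs = c("IFIT1", "IFI27", "IFI44", "IFI44L",
                                 "ISG15", "MX1"),
                        housekeeping = c("GAPDH", "HPRT", "PPIA", "RPL13A"),
                        calibrator) {
  if (length(intersect(isgs, housekeeping))) {
    stop("ISG and housekeeping panels must be disjoint")
  }
  stopifnot(length(isgs) >= 1, length(housekeeping) >= 1,
            is.character(calibrator), length(calibrator) == 1)
  structure(list(isgs = isgs, housekeeping = housekeeping,
                 calibrator = calibrator),
            class = "score_panel")
}

#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are first averaged arithmetically per
#' (sample, gene).  Then, per sample and target gene:
#' dCt = Ct(gene) - mean(Ct over the housekeeping genes of that sample);
#' ddCt = dCt(sample, gene) - dCt(calibrator, gene); RQ = 2^(-ddCt).
#' The calibrator therefore has RQ = 1 for every gene.
#'
#' @param data data.frame with columns `sample`, `group`, `gene`, `ct`
#'   (long format; repeated (sample, gene) rows are technical replicates).
#' @param panel a [score_panel()]; every sample must have every panel gene
#'   measured and the calibrator must be present.
#' @return data.frame of class `rq_table` with columns `sample`, `group`,
#'   `gene`, `dct`, `ddct`, `rq` (target genes only).
#' @export
compute_rq <- function(data, panel) {
  stopifnot(inherits(panel, "score_panel"))
  req <- c("sample", "group", "gene", "ct")
  if (!all(req %in% names(data))) {
    stop("missing column(s): ", paste(setdiff(req, names(data)), collapse = ", "))
  }
  if (any(!is.finite(data$ct) | data$ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  # average technical replicates
  agg <- stats::aggregate(ct ~ sample + group + gene, data = data, FUN = mean)

  samples <- unique(agg$sample)
  if (!panel$calibrator %in% samples) {
    stop("calibrator sample not found: ", panel$calibrator)
  }
  need <- c(panel$isgs, panel$housekeeping)
  gaps <- unlist(lapply(samples, function(s) {
    miss <- setdiff(need, agg$gene[agg$sample == s])
    if (length(miss)) paste0(s, ": ", paste(miss, collapse = ",")) else NULL
  }))
  if (length(gaps)) {
    stop("sample(s) missing panel gene(s) - ", paste(gaps, collapse = "; "))
  }

  hk_mean <- vapply(samples, function(s) {
    mean(agg$ct[agg$sample == s & agg$gene %in% panel$housekeeping])
  }, numeric(1))
  names(hk_mean) <- samples

  tgt <- agg[agg$gene %in% panel$isgs, , drop = FALSE]
  tgt$dct <- tgt$ct - hk_mean[tgt$sample]
  cal <- tgt[tgt$sample == panel$calibrator, c("gene", "dct")]
  cal_dct <- stats::setNames(cal$dct, cal$gene)
  tgt$ddct <- tgt$dct - cal_dct[tgt$gene]
  tgt$rq <- 2^(-tgt$ddct)
  out <- tgt[order(tgt$sample, tgt$gene),
             c("sample", "group", "gene", "dct", "ddct", "rq")]
  rownames(out) <- NULL
  class(out) <- c("rq_table", "data.frame")
  out
}

#' Per-sample type I interferon score
#'
#' The score of a sample is the median of its six ISG relative
#' quantifications (even-count medians are the mean of the two central
#' values); the calibrator scores 1 by construction.
#'
#' @param rq an `rq_table` from [compute_rq()].
#' @param panel the [score_panel()] used.
#' @return data.frame with columns `sample`, `group`, `ifn_score`.
#' @export
score_samples <- function(rq, panel) {
  stopifnot(inherits(panel, "score_panel"))
  rq <- rq[rq$gene %in% panel$isgs, , drop = FALSE]
  samples <- unique(rq$sample)
  miss <- unlist(lapply(samples, function(s) {
    m <- setdiff(panel$isgs, rq$gene[rq$sample == s])
    if (length(m)) paste0(s, ": ", paste(m, collapse = ",")) else NULL
  }))
  if (length(miss)) stop("sample(s) missing ISG(s) - ",
                         paste(miss, collapse = "; "))
  out <- do.call(rbind, lapply(samples, function(s) {
    rows <- rq[rq$sample == s, ]
    data.frame(sample = s, group = rows$group[1],
               ifn_score = stats::median(rows$rq))
  }))
  out <- out[order(out$sample), ]
  rownames(out) <- NULL
  out
}

#' Two-group Mann-Whitney U comparison
#'
#' Compares the scores of two groups by the Mann-Whitney U (Wilcoxon
#' rank-sum) test.  For total sample sizes up to `exact_limit` the
#' two-sided p-value is exact, obtained by enumerating all assignments of
#' the pooled mid-ranks to the first group and summing the probability of
#' U values at least as far from the null mean `n1*n2/2` as observed (the
#' permutation distribution of U is symmetric around that mean, ties
#' included).  Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param scores data.frame with columns `ifn_score` (or `score`/`value`)
#'   and `group`, or a numeric vector with `groups` supplied separately.
#' @param groups optional group labels when `scores` is a numeric vector.
#' @param exact_limit maximum `n1 + n2` for full enumeration (default 20).
#' @return List with `U` (first group's U statistic), `p_value`,
#'   `method` (`"exact enumeration"` or `"normal approximation"`),
#'   `n1`, `n2`.
#' @export
compare_groups <- function(scores, groups = NULL, exact_limit = 20) {
  if (is.data.frame(scores)) {
    col <- intersect(c("ifn_score", "score", "value"), names(scores))[1]
    if (is.na(col) || !"group" %in% names(scores)) {
      stop("data.frame input needs a score column and a 'group' column")
    }
    groups <- scores$group
    scores <- scores[[col]]
  }
  stopifnot(length(scores) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  x <- scores[groups == lev[1]]
  y <- scores[groups == lev[2]]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")

  r <- rank(c(x, y))  # mid-ranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev <- abs(U - mu)

  if (n1 + n2 <= exact_limit) {
    idx <- utils::combn(n1 + n2, n1)
    usub <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(usub - mu) >= dev - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (dev - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method, n1 = n1, n2 = n2)
}
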