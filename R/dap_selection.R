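#' Select differentially abundant proteins
#'
#' Filters a DAP table at the usual proteomics thresholds: p-value at most
#' `p_max` and an effective ratio fold-change of at least `min_fold` in
#' either direction (ratio >= `min_fold` or <= `1/min_fold`; on the log2
#' scale, |lfc| >= log2(`min_fold`)).  Both comparisons are inclusive.
#'
#' @param table data.frame with columns `protein`, `fold_change`, `p_value`.
#' @param p_max maximum p-value kept, inclusive (default 0.05).
#' @param min_fold minimum ratio fold-change kept, inclusive (default 2).
#' @param fc_scale `"ratio"` or `"log2"`; must be declared, never guessed.
#' @return The qualifying rows with an added `direction` column
#'   (`"up"`/`"down"`) and a `log2_fc` column.
#' @export
select_daps <- function(table, p_max = 0.05, min_fold = 2,
                        fc_scale = c("ratio", "log2")) {
  fc_scale <- match.arg(fc_scale)
  req <- c("protein", "fold_change", "p_value")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(min_fold >= 1, p_max >= 0, p_max <= 1)
  fc <- as.numeric(table$fold_change)
  if (fc_scale == "ratio") {
    bad <- which(!is.na(fc) & fc <= 0)
    if (length(bad)) {
      stop("non-positive ratio fold-change in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    lfc <- log2(fc)
  } else {
    lfc <- fc
  }
  keep <- !is.na(lfc) & !is.na(table$p_value) &
    table$p_value <= p_max & abs(lfc) >= log2(min_fold)
  out <- table[keep, , drop = FALSE]
  out$log2_fc <- lfc[keep]
  out$direction <- ifelse(out$log2_fc >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Proteins commonly differential across replicate comparisons
#'
#' Intersects two or more DAP tables: a protein is retained when it passes
#' |log2 fold-change| > `fc_min_log2` AND p-value < `p_max` in *every* table
#' (both strict inequalities).  Direction consistency across tables is only
#' required when `consistent_direction = TRUE`.
#'
#' @param tables list of >= 2 data.frames with columns `protein`,
#'   `fold_change`, `p_value`.
#' @param fc_scales character vector (recycled) declaring each table's
#'   fold-change scale, `"ratio"` or `"log2"`.
#' @param fc_min_log2 strict |log2 fc| threshold (default 0.5).
#' @param p_max strict p-value threshold (default 0.05).
#' @param consistent_direction require the same sign of log2 fc in every
#'   table (default FALSE).
#' @return Sorted character vector of protein ids (possibly empty).
#' @export
common_daps <- function(tables, fc_scales, fc_min_log2 = 0.5, p_max = 0.05,
                        consistent_direction = FALSE) {
  if (!is.list(tables) || length(tables) < 2) {
    stop("need at least two DAP tables")
  }
  fc_scales <- rep_len(match.arg(fc_scales, c("ratio", "log2"),
                                 several.ok = TRUE),
                       length(tables))
  pass <- vector("list", length(tables))
  sign_of <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    req <- c("protein", "fold_change", "p_value")
    if (!all(req %in% names(tb))) {
      stop("table ", i, " missing column(s): ",
           paste(setdiff(req, names(tb)), collapse = ", "))
    }
    fc <- as.numeric(tb$fold_change)
    if (fc_scales[i] == "ratio") {
      bad <- which(!is.na(fc) & fc <= 0)
      if (length(bad)) {
        stop("table ", i, ": non-positive ratio fold-change in row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      lfc <- log2(fc)
    } else {
      lfc <- fc
    }
    ok <- !is.na(lfc) & !is.na(tb$p_value) &
      abs(lfc) > fc_min_log2 & tb$p_value < p_max
    pass[[i]] <- as.character(tb$protein[ok])
    sign_of[[i]] <- stats::setNames(sign(lfc[ok]), tb$protein[ok])
  }
  common <- Reduce(intersect, pass)
  if (consistent_direction && length(common)) {
    same <- vapply(common, function(p) {
      s <- vapply(sign_of, function(m) m[[p]], numeric(1))
      length(unique(s)) == 1
    }, logical(1))
    common <- common[same]
  }
  sort(common)
}
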