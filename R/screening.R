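#' Load an odorant score table
#'
#' Delimited text with required columns \code{id}, \code{score}
#' (docking score, kcal/mol, more negative = stronger binding),
#' \code{mol_weight} (g/mol), \code{volume} (Angstrom^3), \code{logP},
#' and optional \code{chem_class}.
#'
#' @param path file path (tab/whitespace or comma delimited).
#' @return object of class \code{odor_table} (validated data.frame).
#' @export
load_odor_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) == 1)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "score", "mol_weight", "volume", "logP")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("odor table format error: missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("score", "mol_weight", "volume", "logP")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]]))
      stop("odor table format error: non-numeric ", col)
  }
  if (anyDuplicated(df$id))
    stop("odor table format error: duplicate id '",
         df$id[duplicated(df$id)][1], "'")
  if (any(df$volume <= 0)) stop("odor table validation error: volume must be > 0")
  if (any(df$mol_weight <= 0))
    stop("odor table validation error: mol_weight must be > 0")
  if (is.null(df$chem_class)) df$chem_class <- "other"
  structure(df, class = c("odor_table", "data.frame"))
}

#' Top fraction of records by a molecular descriptor
#'
#' Ranks records by a descriptor and returns the ids of the top
#' \code{floor(n * fraction)} (132 records at fraction 1/3 give 44).
#' Ties are broken by id order for determinism.
#'
#' @param records an \code{odor_table} (or data.frame with \code{id} and
#'   the descriptor).
#' @param descriptor one of \code{"mol_weight"}, \code{"volume"},
#'   \code{"logP"}.
#' @param fraction in (0, 1] (default 1/3).
#' @param direction \code{"descending"} (default; large first) or
#'   \code{"ascending"}.
#' @return character vector of ids, in rank order.
#' @export
top_fraction_subset <- function(records, descriptor = c("mol_weight", "volume", "logP"),
                                fraction = 1/3,
                                direction = c("descending", "ascending")) {
  descriptor <- match.arg(descriptor)
  direction <- match.arg(direction)
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(records) == 0) stop("top_fraction_subset: empty table")
  v <- records[[descriptor]]
  ord <- if (direction == "descending") order(-v, records$id)
         else order(v, records$id)
  k <- floor(nrow(records) * fraction)
  as.character(records$id[ord][seq_len(k)])
}

#' ROC curve and AUC for a ranked score table
#'
#' Ranks records by docking score (more negative first by default) and
#' computes the ROC points and the area under the curve. With ties, the
#' AUC equals the Mann-Whitney probability that a random positive
#' outranks a random negative, ties counted one half.
#'
#' @param records an \code{odor_table}.
#' @param positive_ids character vector of ids labelled positive; both
#'   classes must be nonempty.
#' @param score_orientation \code{"more_negative_first"} (default,
#'   docking convention) or \code{"higher_first"}.
#' @return object of class \code{roc_result}: list with \code{points}
#'   (data.frame fpr, tpr, from (0,0) to (1,1)) and \code{auc}.
#' @export
roc_auc <- function(records, positive_ids,
                    score_orientation = c("more_negative_first", "higher_first")) {
  score_orientation <- match.arg(score_orientation)
  lab <- records$id %in% positive_ids
  if (!any(lab) || all(lab))
    stop("roc_auc: positives and negatives must both be nonempty")
  s <- records$score
  if (score_orientation == "more_negative_first") s <- -s
  # rank-based Mann-Whitney AUC (ties = 1/2)
  r <- rank(s, ties.method = "average")
  n_pos <- sum(lab); n_neg <- sum(!lab)
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # ROC points over distinct thresholds, best score first
  ord <- order(-s)
  sl <- lab[ord]; sv <- s[ord]
  grp <- cumsum(!duplicated(sv))            # tie groups share a threshold
  tp <- cumsum(sl); fp <- cumsum(!sl)
  last <- !duplicated(grp, fromLast = TRUE)
  points <- data.frame(fpr = c(0, fp[last] / n_neg),
                       tpr = c(0, tp[last] / n_pos))
  structure(list(points = points, auc = auc,
                 n_pos = n_pos, n_neg = n_neg,
                 orientation = score_orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d positives, %d negatives, %s)\n",
              x$auc, x$n_pos, x$n_neg, x$orientation))
  invisible(x)
}

#' Score-descriptor trend: binned means and rank correlation
#'
#' Splits the records into equal-count bins over a descriptor and
#' reports the per-bin mean score plus the Spearman rank correlation
#' between descriptor and score over all records (ties handled by
#' average ranks; constant scores give correlation 0).
#'
#' @param records an \code{odor_table}.
#' @param descriptor one of \code{"mol_weight"}, \code{"volume"},
#'   \code{"logP"}.
#' @param n_bins number of equal-count bins (>= 2, <= n).
#' @return list with \code{bins} (data.frame descriptor_mid, mean_score,
#'   n) and \code{spearman_rho}.
#' @export
descriptor_trend <- function(records, descriptor = c("mol_weight", "volume", "logP"),
                             n_bins = 6) {
  descriptor <- match.arg(descriptor)
  n <- nrow(records)
  if (n_bins < 2) stop("descriptor_trend: n_bins must be >= 2")
  if (n_bins > n) stop("descriptor_trend: n_bins exceeds record count")
  v <- records[[descriptor]]
  s <- records$score
  ord <- order(v, records$id)
  grp <- ceiling(seq_len(n) / (n / n_bins))
  grp <- pmin(grp, n_bins)
  bins <- data.frame(
    descriptor_mid = as.numeric(tapply(v[ord], grp, mean)),
    mean_score = as.numeric(tapply(s[ord], grp, mean)),
    n = as.integer(table(grp)))
  rho <- if (stats::sd(s) == 0 || stats::sd(v) == 0) 0
         else suppressWarnings(stats::cor(v, s, method = "spearman"))
  list(bins = bins, spearman_rho = rho, descriptor = descriptor)
}

#' Chemical-class selectivity comparison
#'
#' Per-class score summaries plus two-sided Wilcoxon rank-sum tests for
#' every class pair, with Benjamini-Hochberg adjustment across pairs.
#' Classes with fewer than 2 members are excluded with a warning.
#'
#' @param records an \code{odor_table} with a \code{chem_class} column.
#' @param alpha significance level applied to adjusted p values (0.05).
#' @return list with \code{summary} (per-class n, mean, median),
#'   \code{pairs} (data.frame class_a, class_b, statistic, p_value,
#'   p_adjusted, significant), \code{alpha}.
#' @export
class_selectivity <- function(records, alpha = 0.05) {
  cls <- as.character(records$chem_class)
  sizes <- table(cls)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding singleton class(es): ", paste(small, collapse = ", "))
    keep <- !(cls %in% small)
    records <- records[keep, , drop = FALSE]
    cls <- cls[keep]
  }
  classes <- sort(unique(cls))
  if (length(classes) < 2)
    stop("class_selectivity: need at least 2 classes with >= 2 members")
  summ <- data.frame(
    class = classes,
    n = as.integer(table(cls)[classes]),
    mean_score = as.numeric(tapply(records$score, cls, mean)[classes]),
    median_score = as.numeric(tapply(records$score, cls, stats::median)[classes]))
  cmb <- utils::combn(classes, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- records$score[cls == cmb[1, k]]
    b <- records$score[cls == cmb[2, k]]
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(class_a = cmb[1, k], class_b = cmb[2, k],
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- stats::p.adjust(pairs$p_value, method = "BH")
  pairs$significant <- pairs$p_adjusted < alpha
  list(summary = summ, pairs = pairs, alpha = alpha)
}
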