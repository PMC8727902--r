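#' Kruskal-Wallis comparison of accuracy scores
#'
#' Rank-based nonparametric comparison of two or more independent groups,
#' with the tie correction always applied — accuracy scores pile up at 100,
#' so ties are the rule, not the exception. The H statistic is referred to
#' a chi-square distribution with `k - 1` degrees of freedom (via
#' [stats::kruskal.test()]).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   non-empty, at least 2 distinct values overall).
#' @param labels Optional group labels.
#' @return An object of class `group_comparison` with `h_statistic`, `df`,
#'   `p_value`, `group_labels`, `n_per_group`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857
#' @export
kruskal_wallis <- function(groups, labels = NULL) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group needs at least one observation")
  all_x <- unlist(groups, use.names = FALSE)
  if (!is.numeric(all_x) || anyNA(all_x)) stop("scores must be numeric, no NA")
  if (length(unique(all_x)) < 2L)
    stop("all observations identical: H is undefined (no variance)")
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))

  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(all_x, g)
  structure(list(h_statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = unname(kt$p.value),
                 group_labels = labels,
                 n_per_group = vapply(groups, length, integer(1))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.3f, p = %.4g  [%s; n = %s]\n",
              x$df, x$h_statistic, x$p_value,
              paste(x$group_labels, collapse = " vs "),
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Mean/SD summary of accuracy by condition and group
#'
#' Produces the familiar report shape for intelligibility experiments:
#' per-condition, per-group mean accuracy (%), sample (n-1) standard
#' deviation, and n, plus a pooled `"total"` row per condition.
#'
#' @param results Data frame with at least columns `group` and `accuracy`;
#'   any of `phase`, `rate`, `snr_db`, `hints_mode` present are combined
#'   into the condition key.
#' @return Data frame with columns `condition`, `group`, `mean`, `sd`, `n`.
#' @export
summarize_accuracy <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("empty results")
  if (!all(c("group", "accuracy") %in% names(results)))
    stop("results must have 'group' and 'accuracy' columns")
  acc <- results$accuracy
  if (anyNA(acc) || any(acc < 0 | acc > 100))
    stop("accuracy values must lie in [0, 100]")

  cond_cols <- intersect(c("phase", "rate", "snr_db", "hints_mode"),
                         names(results))
  condition <- if (length(cond_cols))
    do.call(paste, c(results[cond_cols], sep = "/")) else "all"

  cell <- function(a) c(mean = mean(a), sd = if (length(a) > 1) stats::sd(a) else 0,
                        n = length(a))
  keys <- unique(data.frame(condition = condition, group = results$group,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$condition, keys$group), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- condition == keys$condition[i] & results$group == keys$group[i]
    cbind(keys[i, , drop = FALSE], as.data.frame(as.list(cell(acc[sel]))))
  })
  totals <- lapply(unique(keys$condition), function(cc) {
    data.frame(condition = cc, group = "total",
               as.data.frame(as.list(cell(acc[condition == cc]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, totals))
  out <- out[order(out$condition, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# run one contrast, degrading gracefully when a cell has no variance
.try_kw <- function(groups, labels) {
  tryCatch(kruskal_wallis(groups, labels),
           error = function(e)
             structure(list(h_statistic = NA_real_, df = length(groups) - 1L,
                            p_value = NA_real_, group_labels = labels,
                            n_per_group = vapply(groups, length, integer(1)),
                            note = conditionMessage(e)),
                      class = "group_comparison"))
}

#' Run the experiment's standard contrast families
#'
#' Three families of Kruskal-Wallis contrasts on per-utterance accuracy:
#' \describe{
#'   \item{downsampling}{8 kHz vs 48 kHz in the quiet condition (groups
#'     pooled).}
#'   \item{group_no_hints}{PD vs HC at each SNR of the babble sweep,
#'     without hints.}
#'   \item{hints_vs_none}{hinted vs unhinted recognition at each SNR; plus
#'     PD vs HC at each SNR with hints (`group_with_hints`).}
#' }
#' Contrasts whose cells have no variance (e.g. everyone at 100) are
#' reported with `p_value = NA` ("not applicable") rather than failing.
#' No multiple-testing correction is applied by default, matching per-SNR
#' reporting conventions; `p_adjust = "holm"` corrects within each family.
#'
#' @param results Long-format results data frame (see [run_experiment()]):
#'   columns `phase`, `speaker_id`, `group`, `snr_db`, `rate`,
#'   `hints_mode`, `accuracy`.
#' @param alpha Significance level for flagging.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Data frame with one row per contrast: `family`, `condition`,
#'   `h_statistic`, `df`, `p_value`, `significant`.
#' @export
run_contrasts <- function(results, alpha = 0.05,
                          p_adjust = c("none", "holm")) {
  stopifnot(is.data.frame(results))
  p_adjust <- match.arg(p_adjust)
  need <- c("phase", "group", "snr_db", "rate", "hints_mode", "accuracy")
  if (!all(need %in% names(results)))
    stop("results lack required columns: ",
         paste(setdiff(need, names(results)), collapse = ", "))

  out <- list()
  add <- function(family, condition, kw) {
    out[[length(out) + 1L]] <<- data.frame(
      family = family, condition = condition,
      h_statistic = kw$h_statistic, df = kw$df, p_value = kw$p_value,
      stringsAsFactors = FALSE)
  }

  quiet <- results[results$phase == "quiet", , drop = FALSE]
  noise <- results[results$phase == "noise", , drop = FALSE]
  if (nrow(quiet) > 0L) {
    rates <- sort(unique(quiet$rate))
    if (length(rates) < 2L) stop("quiet phase needs two sample rates")
    add("downsampling", paste(rates, collapse = " vs "),
        .try_kw(split(quiet$accuracy, quiet$rate), as.character(rates)))
  }
  if (nrow(noise) > 0L) {
    if (!all(c("PD", "HC") %in% noise$group))
      stop("noise phase must contain both PD and HC records")
    snrs <- unique(noise$snr_db)
    for (s in snrs) {
      at <- noise[noise$snr_db == s, , drop = FALSE]
      nh <- at[at$hints_mode == "none", , drop = FALSE]
      if (nrow(nh))
        add("group_no_hints", paste0("snr ", s),
            .try_kw(list(nh$accuracy[nh$group == "PD"],
                         nh$accuracy[nh$group == "HC"]), c("PD", "HC")))
      if (any(at$hints_mode != "none")) {
        hi <- at[at$hints_mode != "none", , drop = FALSE]
        add("hints_vs_none", paste0("snr ", s),
            .try_kw(list(hi$accuracy, nh$accuracy), c("hints", "none")))
        add("group_with_hints", paste0("snr ", s),
            .try_kw(list(hi$accuracy[hi$group == "PD"],
                         hi$accuracy[hi$group == "HC"]), c("PD", "HC")))
      }
    }
  }
  if (length(out) == 0L) stop("no contrastable conditions present")
  tab <- do.call(rbind, out)
  if (p_adjust == "holm") {
    for (f in unique(tab$family)) {
      sel <- tab$family == f & !is.na(tab$p_value)
      tab$p_value[sel] <- stats::p.adjust(tab$p_value[sel], "holm")
    }
  }
  tab$significant <- !is.na(tab$p_value) & tab$p_value < alpha
  tab
}
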