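#' Log2 fold change between two groups
#'
#' Difference of group means on the log2 scale, case minus control.
#' Antisymmetric under swapping the groups.
#'
#' @param case_values,control_values numeric vectors of log2 intensities.
#' @return a single number, `mean(case) - mean(control)`.
#' @export
log_fold_change <- function(case_values, control_values) {
  if (length(case_values) == 0L || length(control_values) == 0L)
    stop("empty group")
  if (!all(is.finite(case_values)) || !all(is.finite(control_values)))
    stop("non-finite input")
  mean(case_values) - mean(control_values)
}

#' Two-group t-test for one gene
#'
#' Ordinary two-sample t-test with a pooled variance estimate (Welch's
#' unequal-variance form available via `welch = TRUE`). The two-sided
#' p-value comes from the t distribution with `n1 + n2 - 2` degrees of
#' freedom (Welch: Satterthwaite df).
#'
#' Degenerate inputs -- both groups with zero variance -- cannot support a
#' t statistic: equal means give `t = 0, p = 1`, different means give
#' `p = 0`; both are flagged with `degenerate = TRUE`.
#'
#' @param case_values,control_values numeric vectors, at least 2 values
#'   each.
#' @param welch use the unequal-variance (Welch) form.
#' @return list with `t_stat`, `p_raw`, `df`, `degenerate`.
#' @export
two_group_t_test <- function(case_values, control_values, welch = FALSE) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group")
  if (!all(is.finite(case_values)) || !all(is.finite(control_values)))
    stop("non-finite input")
  m1 <- mean(case_values); m2 <- mean(control_values)
  v1 <- stats::var(case_values); v2 <- stats::var(control_values)

  if (v1 == 0 && v2 == 0) {
    if (m1 == m2)
      return(list(t_stat = 0, p_raw = 1, df = n1 + n2 - 2L,
                  degenerate = TRUE))
    return(list(t_stat = sign(m1 - m2) * Inf, p_raw = 0,
                df = n1 + n2 - 2L, degenerate = TRUE))
  }

  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t_stat <- (m1 - m2) / sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t_stat = t_stat, p_raw = 2 * stats::pt(-abs(t_stat), df),
       df = df, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment with monotonicity
#' enforcement; the output is in the same order as the input.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("invalid p-value")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify genes as up/down/ns
#'
#' Applies the DEG decision rule: `up` when the adjusted p-value is below
#' `alpha` and logFC exceeds `lfc_cut`; `down` when the adjusted p-value
#' is below `alpha` and logFC is below `-lfc_cut`; `ns` otherwise. All
#' inequalities are strict, so a gene sitting exactly on a threshold is
#' not called.
#'
#' @param stats_df data frame with numeric columns `logFC` and `p_adj`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_cut absolute log2-fold-change cutoff (default 2).
#' @return `stats_df` with a `status` column (`"up"`, `"down"`, `"ns"`).
#' @export
classify_degs <- function(stats_df, alpha = 0.05, lfc_cut = 2) {
  stopifnot(is.data.frame(stats_df),
            all(c("logFC", "p_adj") %in% names(stats_df)))
  status <- rep("ns", nrow(stats_df))
  status[stats_df$p_adj < alpha & stats_df$logFC > lfc_cut] <- "up"
  status[stats_df$p_adj < alpha & stats_df$logFC < -lfc_cut] <- "down"
  stats_df$status <- status
  stats_df
}

#' Screen a dataset for differentially expressed genes
#'
#' Runs a per-gene two-group t-test (pooled variance by default), adjusts
#' the p-values by Benjamini-Hochberg across all genes of the dataset, and
#' classifies genes by the `p_adj < alpha` and `|logFC| > lfc_cut` rule.
#'
#' @param dataset an [expression_dataset()].
#' @param alpha adjusted-p cutoff.
#' @param lfc_cut log2-fold-change cutoff.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return A `deg_table`: a data frame with one row per gene and columns
#'   `gene`, `dataset`, `logFC`, `t`, `p_raw`, `p_adj`, `status`, carrying
#'   the thresholds in its `"thresholds"` attribute.
#' @export
deg_screen <- function(dataset, alpha = 0.05, lfc_cut = 2, welch = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  case_idx <- dataset$groups == "case"
  vals <- dataset$values
  res <- vapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, case_idx]; y <- vals[i, !case_idx]
    tt <- two_group_t_test(x, y, welch = welch)
    c(mean(x) - mean(y), tt$t_stat, tt$p_raw)
  }, numeric(3))
  out <- data.frame(
    gene = rownames(vals),
    dataset = dataset$dataset_id,
    logFC = res[1L, ],
    t = res[2L, ],
    p_raw = res[3L, ],
    stringsAsFactors = FALSE
  )
  out$p_adj <- benjamini_hochberg(out$p_raw)
  out <- classify_degs(out, alpha = alpha, lfc_cut = lfc_cut)
  rownames(out) <- NULL
  structure(out, thresholds = c(alpha = alpha, lfc_cut = lfc_cut),
            class = c("deg_table", "data.frame"))
}

#' @export
print.deg_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("<deg_table> ", nrow(x), " genes from ",
      paste(unique(x$dataset), collapse = ", "), "\n", sep = "")
  if (!is.null(th))
    cat("  thresholds: p_adj < ", th[["alpha"]],
        ", |logFC| > ", th[["lfc_cut"]], "\n", sep = "")
  cat("  up: ", sum(x$status == "up"),
      "   down: ", sum(x$status == "down"),
      "   ns: ", sum(x$status == "ns"), "\n", sep = "")
  invisible(x)
}

#' Integrate DEG calls across datasets
#'
#' Takes the union of up- and down-regulated genes over several
#' [deg_screen()] tables, removing duplicates by symbol. Each output gene
#' records the datasets that called it and the direction(s); a gene called
#' up in one dataset and down in another is retained and flagged as a
#' conflict rather than dropped, so that the network node set is not
#' silently changed.
#'
#' @param tables list of `deg_table` data frames (or a single table).
#' @return data frame with columns `gene`, `direction` (`"up"`, `"down"`
#'   or `"conflict"`), `datasets` (comma-separated), `n_datasets`,
#'   sorted by gene symbol.
#' @export
integrate_degs <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  if (length(tables) == 0L) stop("no DEG tables supplied")
  hits <- do.call(rbind, lapply(tables, function(t) {
    t <- as.data.frame(t)[, c("gene", "dataset", "status")]
    t[t$status %in% c("up", "down"), , drop = FALSE]
  }))
  if (nrow(hits) == 0L)
    return(data.frame(gene = character(0), direction = character(0),
                      datasets = character(0), n_datasets = integer(0),
                      stringsAsFactors = FALSE))
  sp <- split(hits, hits$gene)
  out <- do.call(rbind, lapply(sp, function(h) {
    dirs <- unique(h$status)
    data.frame(
      gene = h$gene[1L],
      direction = if (length(dirs) > 1L) "conflict" else dirs,
      datasets = paste(sort(unique(h$dataset)), collapse = ","),
      n_datasets = length(unique(h$dataset)),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
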