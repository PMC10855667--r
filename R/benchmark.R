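#' Load a sentence-pair dataset
#'
#' Reads a UTF-8 CSV or TSV with columns `suggestion`, `ground_truth`, and
#' either a single `human` column or `human_1 .. human_k` rater columns
#' (an `id` column is honoured if present; otherwise row numbers are used).
#' Malformed rows — empty sentence on either side, or a non-finite human
#' score — are dropped with a warning naming their line numbers.
#'
#' @param path File path; tab-separated when the extension is `.tsv`,
#'   comma-separated otherwise. Override with `sep`.
#' @param sep Optional field separator.
#' @return A `dataset`: list with `records` (list of [pair_record()]s),
#'   `source`, and `n`.
#' @export
load_dataset <- function(path, sep = NULL) {
  if (!file.exists(path)) err_invalid_input(sprintf("file not found: %s", path))
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          comment.char = "", check.names = FALSE)
  if (nrow(df) == 0L) embedhdp_error("dataset is empty", "embedhdp_empty_dataset")
  need <- c("suggestion", "ground_truth")
  if (!all(need %in% names(df)))
    embedhdp_error(sprintf("missing required column(s): %s",
                           paste(setdiff(need, names(df)), collapse = ", ")),
                   "embedhdp_schema_error")
  human_cols <- if ("human" %in% names(df)) "human"
                else grep("^human_[0-9]+$", names(df), value = TRUE)
  if (length(human_cols) == 0L)
    embedhdp_error("no human score column (need `human` or `human_1..k`)",
                   "embedhdp_schema_error")
  ids <- if ("id" %in% names(df)) as.character(df$id) else as.character(seq_len(nrow(df)))

  records <- vector("list", nrow(df))
  bad <- integer(0)
  for (i in seq_len(nrow(df))) {
    sug <- trimws(as.character(df$suggestion[[i]]))
    gt <- trimws(as.character(df$ground_truth[[i]]))
    hs <- suppressWarnings(as.numeric(unlist(df[i, human_cols])))
    if (!nzchar(sug) || !nzchar(gt) || anyNA(hs) || any(!is.finite(hs))) {
      bad <- c(bad, i + 1L)  # +1: header line
      next
    }
    records[[i]] <- pair_record(sug, gt, human_scores = hs, id = ids[[i]])
  }
  records <- records[!vapply(records, is.null, logical(1))]
  if (length(bad))
    warning(sprintf("dropped %d malformed row(s) at line(s): %s",
                    length(bad), paste(bad, collapse = ", ")))
  if (length(records) == 0L)
    embedhdp_error("no well-formed rows in dataset", "embedhdp_empty_dataset")
  structure(list(records = records, source = path, n = length(records)),
            class = "dataset")
}

#' @export
print.dataset <- function(x, ...) {
  cat("<dataset> ", x$n, " pair(s) from ", x$source, "\n", sep = "")
  invisible(x)
}

#' Aggregate multi-rater human scores
#'
#' @param scores Numeric vector of finite rater scores, length >= 1.
#' @param method `"mean"` (default) or `"median"`.
#' @return Single aggregated score.
#' @export
aggregate_human <- function(scores, method = c("mean", "median")) {
  method <- match.arg(method)
  scores <- as.numeric(scores)
  if (length(scores) == 0L || any(!is.finite(scores)))
    err_invalid_input("`scores` must be a non-empty finite numeric vector")
  if (method == "mean") mean(scores) else stats::median(scores)
}

#' Pearson correlation with contract checks
#'
#' Thin wrapper over [stats::cor()] that enforces the benchmark's
#' preconditions: equal lengths of at least 3 and non-zero variance on both
#' sides (a constant metric has no defined correlation with human scores,
#' and is reported as such rather than as a number).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) err_invalid_input("`x` and `y` lengths differ")
  if (length(x) < 3L) err_invalid_input("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    err_invalid_input("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    embedhdp_error("correlation undefined: zero variance",
                   "embedhdp_undefined_correlation")
  stats::cor(x, y, method = method)
}

# built-in metric panel; each scorer maps (pair, cfg, backend) -> numeric(1)
metric_registry <- function(backend) {
  list(
    embedhdp = function(pair, cfg, backend) embedhdp_score(pair, cfg, backend)$value,
    cosine = function(pair, cfg, backend)
      bow_cosine(cfg_tokenize(cfg, pair$suggestion), cfg_tokenize(cfg, pair$ground_truth)),
    rouge1 = function(pair, cfg, backend)
      rouge_n(cfg_tokenize(cfg, pair$suggestion), cfg_tokenize(cfg, pair$ground_truth), 1)$f,
    rouge2 = function(pair, cfg, backend)
      rouge_n(cfg_tokenize(cfg, pair$suggestion), cfg_tokenize(cfg, pair$ground_truth), 2)$f,
    rougeL = function(pair, cfg, backend)
      rouge_l(cfg_tokenize(cfg, pair$suggestion), cfg_tokenize(cfg, pair$ground_truth))$f,
    bleu = function(pair, cfg, backend)
      bleu(cfg_tokenize(cfg, pair$suggestion), cfg_tokenize(cfg, pair$ground_truth))
  )
}

#' Run the metric-vs-human benchmark
#'
#' Applies the length filter, scores every kept pair with every metric in
#' the panel, and reports each metric's correlation against the aggregated
#' human scores. Pairs that fail inside one metric are excluded from that
#' metric's `n_used` and logged; a metric whose correlation is undefined
#' (constant scores) is reported with `r = NA` and an explanatory message,
#' without aborting the rest of the panel.
#'
#' @param ds A [load_dataset()] result (or `dataset`-shaped list).
#' @param metrics Character vector naming built-in metrics
#'   (`"embedhdp"`, `"cosine"`, `"rouge1"`, `"rouge2"`, `"rougeL"`,
#'   `"bleu"`), and/or a named list mixing those names with scorer
#'   functions such as [make_external_scorer()] adapters.
#' @param cfg A [metric_config()].
#' @param backend An `embedding_backend` (used by the embedhdp scorer).
#' @param aggregate `"mean"` or `"median"` rater aggregation.
#' @param method Correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @return A `benchmark_report`: per-metric `r` and `n_used`, the filter
#'   counts `n_input`, `n_kept`, `n_removed`, and the config digest.
#' @export
run_benchmark <- function(ds, metrics = c("embedhdp", "cosine", "rouge1",
                                          "rougeL", "bleu"),
                          cfg = metric_config(), backend,
                          aggregate = c("mean", "median"),
                          method = c("pearson", "spearman")) {
  aggregate <- match.arg(aggregate)
  method <- match.arg(method)
  if (!is.list(ds) || is.null(ds$records) || length(ds$records) == 0L)
    err_invalid_input("`ds` must be a non-empty dataset")

  registry <- metric_registry(backend)
  if (is.character(metrics)) metrics <- as.list(metrics)
  scorers <- list()
  for (m in metrics) {
    if (is.character(m)) {
      if (!m %in% names(registry))
        err_config(sprintf("unknown metric '%s'", m))
      scorers[[m]] <- registry[[m]]
    } else if (is.function(m)) {
      scorers[[attr(m, "metric_name") %||% "custom"]] <- m
    } else err_config("each metric must be a name or a scorer function")
  }

  flt <- length_filter(ds$records, cfg)
  if (flt$n_kept == 0L)
    embedhdp_error("every pair was removed by the length filter",
                   "embedhdp_empty_after_filter")
  human <- vapply(flt$kept, function(p) {
    if (is.null(p$human_scores))
      err_invalid_input(sprintf("pair '%s' has no human scores", p$id))
    aggregate_human(p$human_scores, aggregate)
  }, 0)

  per_metric <- list()
  for (nm in names(scorers)) {
    vals <- rep(NA_real_, flt$n_kept)
    errors <- character(0)
    for (i in seq_along(flt$kept)) {
      vals[[i]] <- tryCatch(scorers[[nm]](flt$kept[[i]], cfg, backend),
                            error = function(e) {
                              errors <<- c(errors, sprintf(
                                "pair '%s': %s", flt$kept[[i]]$id, conditionMessage(e)))
                              NA_real_
                            })
    }
    ok <- is.finite(vals)
    r <- tryCatch(
      if (sum(ok) >= 3L) pearson_r(vals[ok], human[ok], method) else NA_real_,
      embedhdp_undefined_correlation = function(e) {
        errors <<- c(errors, conditionMessage(e)); NA_real_
      })
    per_metric[[nm]] <- list(r = r, n_used = sum(ok), errors = errors)
  }

  structure(list(per_metric = per_metric,
                 n_input = length(ds$records),
                 n_kept = flt$n_kept, n_removed = flt$n_removed,
                 aggregate = aggregate, method = method,
                 config_digest = config_digest(cfg, backend)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> n_input = ", x$n_input, ", kept = ", x$n_kept,
      ", removed = ", x$n_removed, " (", x$method, " r vs ", x$aggregate,
      " human score)\n", sep = "")
  for (nm in names(x$per_metric)) {
    pm <- x$per_metric[[nm]]
    cat(sprintf("  %-10s r = %s  (n_used = %d)%s\n", nm,
                if (is.na(pm$r)) "NA" else sprintf("%+.4f", pm$r), pm$n_used,
                if (length(pm$errors)) sprintf("  [%d error(s)]", length(pm$errors)) else ""))
  }
  invisible(x)
}

#' Render a benchmark report as a Markdown table
#'
#' @param report A [run_benchmark()] result.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  rows <- vapply(names(report$per_metric), function(nm) {
    pm <- report$per_metric[[nm]]
    sprintf("| %s | %s | %d |", nm,
            if (is.na(pm$r)) "undefined" else sprintf("%.2f", pm$r), pm$n_used)
  }, "")
  c("| Evaluation metric | Correlation coefficient | n |",
    "|---|---|---|", unname(rows))
}
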