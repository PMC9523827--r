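# Readers and writers: long-format trial tables in, TSV/JSON reports out,
# YAML-or-JSON design and model configuration.

#' Read a long-format trial table
#'
#' Expects a delimited file (TSV or CSV by extension) with header columns
#' `arm`, `value`, `stage`. Ordinal endpoints given as labels must be
#' declared through `levels` (an ordered character vector); labels are then
#' mapped to the codes `1..length(levels)`. Levels are never inferred from
#' the sort order of the strings.
#'
#' @param path file path.
#' @param levels optional ordered category labels for non-numeric values.
#' @param K total number of planned analyses (default: largest stage seen).
#' @return A [two_arm_stage_data] object.
#' @export
read_trial_table <- function(path, levels = NULL, K = NULL) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("arm", "value", "stage"))
    if (!col %in% names(df))
      stop_parse(sprintf("missing column '%s' in %s", col, path))
  val <- df$value
  if (!is.numeric(val)) {
    if (is.null(levels))
      stop_parse("non-numeric 'value' column but no ordered level list given")
    idx <- match(as.character(val), levels)
    if (anyNA(idx))
      stop_parse(sprintf("row %d: value '%s' not in the declared levels",
                         which(is.na(idx))[1], val[which(is.na(idx))[1]]))
    val <- idx
  }
  bad_arm <- which(!df$arm %in% c(1, 2))
  if (length(bad_arm))
    stop_parse(sprintf("row %d: arm must be 1 or 2", bad_arm[1]))
  bad_stage <- which(is.na(suppressWarnings(as.integer(df$stage))) |
                       df$stage < 1)
  if (length(bad_stage))
    stop_parse(sprintf("row %d: stage must be a positive integer",
                       bad_stage[1]))
  two_arm_stage_data(arm = as.integer(df$arm), value = as.numeric(val),
                     stage = as.integer(df$stage),
                     K = if (is.null(K)) max(as.integer(df$stage)) else K)
}

flatten_result <- function(x) {
  if (inherits(x, "gsr_monitoring")) {
    df <- as.data.frame(x)
    attr(df, "row.names") <- seq_len(nrow(df))
    df
  } else if (inherits(x, "gsr_sim_result")) {
    sim_result_table(x)
  } else if (inherits(x, "gsr_power")) {
    data.frame(method = x$method, spending = x$spending, alpha = x$alpha,
               t = x$t, stage = seq_along(x$stage_n), N = x$stage_n,
               crit = x$crit, info = x$info, power = x$power)
  } else if (inherits(x, "gsr_samplesize")) {
    data.frame(method = x$method, spending = x$spending, alpha = x$alpha,
               t = x$t, stage = seq_along(x$stage_n), N = x$stage_n,
               target_power = x$target_power, power = x$power)
  } else if (is.data.frame(x)) {
    x
  } else {
    stop_invalid_input("no tabular representation for this object")
  }
}

#' Write a result report
#'
#' Serializes monitoring, power, sample-size or simulation results as a
#' delimited table or JSON. Numeric fields round-trip at full double
#' precision.
#'
#' @param x result object (`gsr_monitoring`, `gsr_sim_result`, `gsr_power`,
#'   `gsr_samplesize`, or a plain data frame).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- flatten_result(x)
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    out <- df
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v)
      vapply(v, function(z) format(z, digits = 17, scientific = FALSE,
                                   trim = TRUE), character(1)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

parse_model_block <- function(blk) {
  fam <- blk$family %||% stop_parse("model block needs a 'family' field")
  if (fam == "normal") {
    dist_normal(blk$mean1 %||% 0, blk$sd1 %||% 1,
                blk$mean2 %||% 0, blk$sd2 %||% 1)
  } else if (fam %in% c("latent_beta_ordinal", "beta-ordinal")) {
    dist_latent_beta_ordinal(blk$alpha1, blk$beta1, blk$alpha2, blk$beta2,
                             cuts = unlist(blk$cuts %||% (0.2 * (0:5))))
  } else if (fam %in% c("empirical_pmf", "pmf")) {
    dist_pmf(unlist(blk$pmf1), unlist(blk$pmf2))
  } else stop_parse(sprintf("unknown model family '%s'", fam))
}

#' Read a design / model configuration file
#'
#' YAML or JSON (by extension) with a `design` block (`K`, `alpha`,
#' `spending`, `imax`, optional `method`) and optionally a `model` block
#' (`family` plus its parameters) and `levels` for ordinal label mapping.
#'
#' @param path configuration file path.
#' @return List with elements `design` (a `gsr_design`), `method`, `model`
#'   (a `gsr_model` or `NULL`) and `levels`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  db <- cfg$design %||% stop_parse("configuration needs a 'design' block")
  design <- sequential_design(db$K, db$alpha %||% 0.025,
                              db$spending %||% "obrien_fleming", db$imax)
  model <- if (!is.null(cfg$model)) parse_model_block(cfg$model) else NULL
  list(design = design, method = db$method %||% "bm", model = model,
       levels = unlist(cfg$levels))
}
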