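# CSV/TSV readers and writers for hypnograms, spike times, dose blocks,
# PK profiles, Ct tables and bout tables.
#
# Hypnogram dialect: one row per epoch, columns `epoch_index` (0-based)
# and `state`; epoch length and ZT anchor in a leading comment line
# "#epoch_s=10 #start_zt=0".

read_delim_auto <- function(path) {
  first <- readLines(path, n = 5L)
  first <- first[!startsWith(first, "#")]
  sep <- if (grepl("\t", first[1])) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
}

#' Read a typed analysis table from CSV/TSV
#'
#' Dispatches on a named schema and returns the validated domain object.
#'
#' @param path CSV or TSV file (separator auto-detected; lines starting
#'   with `#` are treated as comments, except the hypnogram metadata line).
#' @param schema one of `"hypnogram"`, `"spikes"`, `"blocks"`, `"pk"`,
#'   `"ct"`, `"bouts"`.
#' @param duration_s for `schema = "spikes"`: recording duration; defaults
#'   to the last spike time rounded up to the next second.
#' @return `hypnogram` / `spike_train` / block `data.frame` /
#'   `pk_profile` / `ct_table` / bout `data.frame` according to `schema`.
#' @export
read_table <- function(path, schema = c("hypnogram", "spikes", "blocks",
                                        "pk", "ct", "bouts"),
                       duration_s = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("read_table: file not found: ", path)
  df <- read_delim_auto(path)
  switch(schema,
    hypnogram = {
      require_columns(df, c("epoch_index", "state"), "hypnogram table")
      meta <- grep("^#", readLines(path, n = 3L), value = TRUE)
      epoch_s <- 10; start_zt <- 0
      if (length(meta)) {
        m1 <- regmatches(meta[1], regexec("epoch_s=([0-9.]+)", meta[1]))[[1]]
        m2 <- regmatches(meta[1], regexec("start_zt=([0-9.]+)", meta[1]))[[1]]
        if (length(m1) == 2L) epoch_s <- as.numeric(m1[2])
        if (length(m2) == 2L) start_zt <- as.numeric(m2[2])
      }
      df <- df[order(df$epoch_index), , drop = FALSE]
      hypnogram(df$state, epoch_s = epoch_s, start_zt = start_zt)
    },
    spikes = {
      require_columns(df, "time_s", "spike table")
      if (nrow(df) > 1L && any(diff(df$time_s) <= 0))
        stop("spike table: times not increasing at row ",
             which(diff(df$time_s) <= 0)[1] + 1L)
      if (is.null(duration_s))
        duration_s <- if (nrow(df)) ceiling(max(df$time_s) + 1e-9) else 1
      spike_train(df$time_s, duration_s = duration_s)
    },
    blocks = {
      require_columns(df, c("label", "start_s", "end_s"), "block table")
      if (is.null(df$dose_mg_per_kg)) df$dose_mg_per_kg <- NA_real_
      df[, c("label", "start_s", "end_s", "dose_mg_per_kg")]
    },
    pk = {
      require_columns(df, c("time_min", "conc_ng_ml"), "pk table")
      pk_profile(df$time_min, df$conc_ng_ml)
    },
    ct = {
      require_columns(df, c("sample_id", "group", "gene", "ct"), "ct table")
      ct_table(df$sample_id, df$group, df$gene, df$ct)
    },
    bouts = {
      require_columns(df, c("state", "start_epoch", "n_epochs",
                            "duration_min", "phase"), "bout table")
      df
    })
}

#' Write a hypnogram to CSV
#'
#' Writes the self-describing dialect read back by
#' `read_table(schema = "hypnogram")`: a `#epoch_s=... #start_zt=...`
#' comment line, then `epoch_index` (0-based) and `state` columns.
#'
#' @param h a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#epoch_s=%g #start_zt=%g",
                     attr(h, "epoch_s"), attr(h, "start_zt")), con)
  utils::write.csv(
    data.frame(epoch_index = seq_along(h) - 1L, state = as.character(h)),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spike times (and optionally dose blocks) to CSV
#'
#' @param train a [spike_train()].
#' @param path output path for the spike times (`time_s` column).
#' @param blocks_path optional output path for the block table.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(train, path, blocks_path = NULL) {
  stopifnot(inherits(train, "spike_train"))
  utils::write.csv(data.frame(time_s = train$times_s), path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(blocks_path)) {
    if (is.null(train$blocks))
      stop("write_spikes_csv: train has no blocks")
    utils::write.csv(train$blocks, blocks_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Write a PK profile to CSV
#' @param profile a [pk_profile()].
#' @param path output path (`time_min`, `conc_ng_ml` columns).
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(profile, path) {
  stopifnot(inherits(profile, "pk_profile"))
  utils::write.csv(data.frame(time_min = profile$times_min,
                              conc_ng_ml = profile$conc_ng_per_ml),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Ct table to CSV
#' @param ct a [ct_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
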