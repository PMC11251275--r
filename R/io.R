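#' Write titration traces as long-format CSV
#'
#' Columns: `sample_id, cabp_nM, dilution, time_s, a340` (UTF-8, header,
#' '.' decimal). One row per read.
#'
#' @param series A `titration_series` or list of them.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  rows <- lapply(series, function(ts) {
    do.call(rbind, lapply(ts$traces, function(tr) {
      data.frame(sample_id = tr$sample_id, cabp_nM = tr$cabp_conc,
                 dilution = tr$dilution, time_s = tr$times,
                 a340 = tr$a340, stringsAsFactors = FALSE)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format trace CSV into absorbance traces
#'
#' Validates as it parses: required header, numeric cells, non-negative
#' CABP, strictly increasing times per trace after canonical time sort.
#' Malformed input raises a descriptive error naming the offending rows
#' rather than silently coercing.
#'
#' @param path CSV with header `sample_id, cabp_nM, dilution, time_s,
#'   a340`.
#' @return List of [absorbance_trace()], grouped by (sample_id, cabp_nM)
#'   in file order (the zero-CABP replicates of the standard ladder are
#'   distinguished by a `rep` counter attribute).
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("sample_id", "cabp_nM", "dilution", "time_s", "a340")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trace file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("cabp_nM", "dilution", "time_s", "a340")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric or missing '", col, "' at data row ", bad[1],
           call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$cabp_nM < 0))
    stop("negative CABP concentration at data row ",
         which(df$cabp_nM < 0)[1], call. = FALSE)

  # group wells by (sample_id, cabp_nM); replicate wells at the same CABP
  # (the two zero-CABP wells of the standard ladder) repeat every time
  # point, and are separated by occurrence order, which reconstructs the
  # replicates of a sequentially written file and is deterministic for any
  # row order
  key <- paste(df$sample_id, df$cabp_nM, sep = "\r")
  rep_idx <- stats::ave(seq_len(nrow(df)),
                        key, df$time_s, FUN = seq_along)
  gkey <- paste(key, rep_idx, sep = "\r")
  idx <- split(seq_len(nrow(df)), factor(gkey, levels = unique(gkey)))
  lapply(idx, function(ii) {
    o <- ii[order(df$time_s[ii])]
    absorbance_trace(df$sample_id[o[1]], df$cabp_nM[o[1]],
                     df$dilution[o[1]], df$time_s[o], df$a340[o])
  })
}

#' Group traces into titration series by sample
#'
#' @param traces List of [absorbance_trace()] (e.g. from [read_traces()]).
#' @param constants Shared [assay_constants()].
#' @param batches Optional named vector mapping sample_id to batch_id.
#' @param reference_id Optional sample_id of the internal standard.
#' @return List of [titration_series()], one per sample.
#' @export
traces_to_series <- function(traces, constants = assay_constants(),
                             batches = NULL, reference_id = NULL) {
  ids <- vapply(traces, `[[`, character(1), "sample_id")
  lapply(split(traces, factor(ids, levels = unique(ids))), function(trs) {
    sid <- trs[[1]]$sample_id
    titration_series(
      sid, trs, constants, dilution = trs[[1]]$dilution,
      batch_id = if (!is.null(batches) && sid %in% names(batches))
        batches[[sid]] else "batch1",
      is_reference = identical(sid, reference_id)
    )
  })
}

#' Write a panel table as TSV
#'
#' @param panel A `panel_table` data.frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

norm_label <- function(x, vocab, col) {
  lx <- tolower(trimws(x))
  # tolerate common synonyms
  if ("yes" %in% vocab) {
    lx[lx %in% c("true", "yes", "1", "carboxysome")] <- "yes"
    lx[lx %in% c("false", "no", "0", "none")] <- "no"
  }
  if ("photo" %in% vocab) {
    lx[lx %in% c("phototroph", "phototrophy", "photo")] <- "photo"
    lx[lx %in% c("chemotroph", "chemotrophy", "chemo")] <- "chemo"
  }
  bad <- !is.na(lx) & !(lx %in% vocab)
  if (any(bad))
    stop("unknown ", col, " label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  lx
}

#' Read a variant panel table (optionally joining rates and metadata)
#'
#' Reads delimited text (TSV or CSV, sniffed from the header line) with a
#' configurable column map, normalizes controlled-vocabulary labels
#' case-insensitively, and -- when a second file is given -- joins rates
#' and metadata on the variant id (inner join; unmatched ids are reported
#' via the `misses` attribute).
#'
#' @param path Rates table.
#' @param meta_path Optional metadata table to join on the variant id.
#' @param column_map Named character vector mapping the canonical names
#'   (`variant_id`, `kcat`, `trophic_mode`, `carboxysome`, `clade`,
#'   `subset`, `host_temperature`) to the file's column names. Unmapped
#'   optional columns are filled with NA.
#' @param activity_threshold Rate defining "active" (s^-1).
#' @return A `panel_table` data.frame.
#' @export
read_panel <- function(path, meta_path = NULL,
                       column_map = c(variant_id = "variant_id",
                                      kcat = "kcat"),
                       activity_threshold = 0.5) {
  read_any <- function(p) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
    hdr <- readLines(p, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
    read.delim(p, sep = sep, stringsAsFactors = FALSE)
  }
  df <- read_any(path)
  if (!is.null(meta_path)) {
    meta <- read_any(meta_path)
    idcol <- unname(column_map[["variant_id"]])
    if (!(idcol %in% names(df)) || !(idcol %in% names(meta)))
      stop("variant id column '", idcol, "' must be in both files",
           call. = FALSE)
    misses <- list(rates_only = setdiff(df[[idcol]], meta[[idcol]]),
                   meta_only = setdiff(meta[[idcol]], df[[idcol]]))
    df <- merge(df, meta, by = idcol)
    attr_misses <- misses
  } else attr_misses <- NULL

  pick <- function(canon, required = FALSE) {
    src <- if (canon %in% names(column_map)) column_map[[canon]] else canon
    if (src %in% names(df)) return(df[[src]])
    if (required)
      stop("required column '", canon, "' (mapped to '", src,
           "') not found", call. = FALSE)
    rep(NA, nrow(df))
  }
  id <- as.character(pick("variant_id", required = TRUE))
  if (anyDuplicated(id))
    stop("duplicate variant id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  kcat <- suppressWarnings(as.numeric(pick("kcat", required = TRUE)))

  out <- data.frame(
    variant_id = id, kcat = kcat,
    active = !is.na(kcat) & kcat > activity_threshold,
    status = ifelse(is.na(kcat), "insoluble", "active"),
    trophic_mode = norm_label(as.character(pick("trophic_mode")),
                              c("photo", "chemo"), "trophic_mode"),
    carboxysome = norm_label(as.character(pick("carboxysome")),
                             c("yes", "no"), "carboxysome"),
    clade = norm_label(as.character(pick("clade")),
                       c("alpha_cyano", "beta_cyano", "ccm_proteo",
                         "other"), "clade"),
    subset = as.character(pick("subset")),
    group = NA_character_,
    host_temperature = suppressWarnings(
      as.numeric(pick("host_temperature"))),
    stringsAsFactors = FALSE
  )
  out$status[!is.na(kcat) & kcat <= activity_threshold] <- "inactive"
  attr(out, "misses") <- attr_misses
  class(out) <- c("panel_table", "data.frame")
  out
}

#' Read a run configuration (JSON)
#'
#' Unknown top-level keys are rejected so typos cannot silently disable an
#' option.
#'
#' @param path JSON file.
#' @return A named list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "out_dir", "constants", "panel_spec", "windowing",
             "thresholds", "clustering", "statistics", "attribution",
             "traces_file", "panel_file", "simulate")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}
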