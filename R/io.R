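SESSION_COLUMNS <- c("trial", "color", "shape", "outcome",
                     "relevant_dimension", "rewarded_manifestation",
                     "expected", "rt_ms", "responded")

#' Coerce a trial table to a task object
#'
#' Validates the required columns and manifestation codes and attaches the
#' `"isp_task"` class so the table can be fed to [run_two_branch()] and
#' [simulate_subject()].
#'
#' @param data data frame with at least `trial`, `color`, `shape`,
#'   `outcome`, `relevant_dimension`, `rewarded_manifestation`, `expected`.
#' @return an `"isp_task"` tibble.
#' @export
as_isp_task <- function(data) {
  need <- setdiff(SESSION_COLUMNS, c("rt_ms", "responded"))
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  bad_col <- which(!data$color %in% COLOR_LEVELS)
  bad_shp <- which(!data$shape %in% SHAPE_LEVELS)
  bad_out <- which(!data$outcome %in% c("coin", "circle"))
  for (b in list(c("color", bad_col[1]), c("shape", bad_shp[1]),
                 c("outcome", bad_out[1]))) {
    if (!is.na(b[2])) {
      abort(paste0("invalid ", b[1], " value on row ", b[2]))
    }
  }
  if (any(is.na(data$trial)) || any(data$trial < 1) ||
      any(data$trial != as.integer(data$trial))) {
    abort("`trial` must hold positive 1-based integers")
  }
  out <- tibble::as_tibble(data)
  if (!inherits(out, "isp_task")) class(out) <- c("isp_task", class(out))
  out
}

#' Write a session (task plus behaviour) to a tidy TSV
#'
#' One row per trial with 1-based trial indices. Missing reaction times are
#' written as `NA`.
#'
#' @param data trial table; a `subject_id` column and the derived `block`
#'   and `half` columns are written when present.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(data, path) {
  cols <- intersect(c("subject_id", "block", "half", SESSION_COLUMNS,
                      "valid", "log_rt"), names(data))
  missing <- setdiff(setdiff(SESSION_COLUMNS, c("rt_ms", "responded")),
                     names(data))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(dplyr::select(tibble::as_tibble(data),
                                 dplyr::all_of(cols)), path)
  invisible(path)
}

#' Read a session TSV
#'
#' Validates the documented schema and reports violations with row numbers.
#'
#' @param path TSV file with a header; required columns: `trial`, `color`,
#'   `shape`, `outcome`, `relevant_dimension`, `rewarded_manifestation`,
#'   `expected`, `rt_ms`, `responded` (plus optional `subject_id`, `block`,
#'   `half`).
#' @param block_length used to derive `block` when the column is absent.
#' @return an `"isp_task"` tibble including the behaviour columns.
#' @export
read_session <- function(path, block_length = 20L) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(SESSION_COLUMNS, names(raw))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  num_field <- function(x, name, allow_na = FALSE) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !(allow_na & (is.na(x) | x == "NA")))
    if (length(bad)) {
      abort(paste0("non-numeric `", name, "` on row ", bad[1]))
    }
    out
  }
  raw$trial <- num_field(raw$trial, "trial")
  raw$rt_ms <- num_field(raw$rt_ms, "rt_ms", allow_na = TRUE)
  raw$responded <- as.logical(toupper(raw$responded))
  if (anyNA(raw$responded)) {
    abort(paste0("non-logical `responded` on row ",
                 which(is.na(raw$responded))[1]))
  }
  if ("block" %in% names(raw)) {
    raw$block <- num_field(raw$block, "block")
  } else {
    raw$block <- ceiling(raw$trial / block_length)
  }
  if ("half" %in% names(raw)) {
    raw$half <- num_field(raw$half, "half")
  } else {
    raw$half <- ifelse(raw$relevant_dimension == raw$relevant_dimension[1],
                       1, 2)
  }
  as_isp_task(raw)
}

#' Write analysis artifacts with a manifest
#'
#' Writes each element of `results` to `out_dir` (data frames as TSV,
#' matrices as TSV with a leading row-name column, everything else as JSON)
#' plus a `manifest.json` recording the package version, the written files
#' with their MD5 checksums, a hash of the result contents and seed, the
#' seed itself and a timestamp. Identical inputs yield identical manifests
#' up to the timestamp; changing the contents or the seed changes the hash.
#'
#' @param results named list of artifacts.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed to record.
#' @return the manifest, invisibly.
#' @export
save_results <- function(results, out_dir, seed = NULL) {
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("`results` must be a fully named list")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(x, f)
    } else if (is.matrix(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      df <- tibble::as_tibble(as.data.frame(unclass(x)),
                              .name_repair = "minimal")
      df <- dplyr::mutate(df, row = rownames(x) %||%
                            as.character(seq_len(nrow(x))), .before = 1)
      readr::write_tsv(df, f)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           force = TRUE, pretty = TRUE)
    }
    files[nm] <- f
  }
  manifest <- list(
    package = "relsal",
    version = as.character(utils::packageVersion("relsal")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    content_hash = rlang::hash(list(results = results, seed = seed)),
    files = purrr::imap(files, function(f, nm) {
      list(name = nm, path = basename(f),
           md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
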