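#' Read an IBI trace from a text file
#'
#' Two dialects are supported. The canonical dialect is comma-delimited with
#' header `beat_time_s,ibi_ms,corrected,flat,stair,out_of_bounds,activity`
#' and optional `#key=value` metadata comment lines (`individual_id`,
#' `tag_id`, `session_start` and the covariates `day_of_year`,
#' `time_of_day`, `deploy_day`, `mass_kg`, `temperature_c`). The `bare`
#' dialect is the common RR-export convention: one IBI in integer
#' milliseconds per line, no header; beat times are reconstructed as the
#' cumulative IBI sum and all flags default to false.
#'
#' @param path file to read.
#' @param dialect `"canonical"` or `"bare"`.
#' @return an [ibi_trace].
#' @export
read_trace <- function(path, dialect = c("canonical", "bare")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "bare") return(parse_bare_trace(lines, path))
  parse_canonical_trace(lines, path)
}

parse_bare_trace <- function(lines, path) {
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad))
    stop("parse error at line ", lineno[bad[1]], " of ", path,
         ": IBI must be a positive number, got '",
         trimws(lines[keep][bad[1]]), "'")
  ibi_trace(vals)
}

parse_canonical_trace <- function(lines, path) {
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  meta <- list()
  for (m in sub("^#", "", meta_lines)) {
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!is_meta]
  body_lineno <- which(!is_meta)
  body_keep <- nzchar(trimws(body))
  body <- body[body_keep]
  body_lineno <- body_lineno[body_keep]
  header <- "beat_time_s,ibi_ms,corrected,flat,stair,out_of_bounds,activity"
  if (!length(body) || trimws(body[1]) != header)
    stop("parse error in ", path, ": expected header '", header, "'")
  rows <- body[-1]
  rowno <- body_lineno[-1]
  cov <- meta[intersect(names(meta), COVARIATE_NAMES)]
  cov <- lapply(cov, as.numeric)
  if (!length(rows)) {
    return(ibi_trace(numeric(0),
                     individual_id = meta$individual_id %||% "",
                     tag_id = meta$tag_id %||% "",
                     session_start = meta$session_start %||% NA_character_,
                     covariates = cov))
  }
  parts <- strsplit(rows, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7))
    stop("parse error at line ", rowno[which(nf != 7)[1]], " of ", path,
         ": expected 7 fields")
  m <- matrix(unlist(parts), ncol = 7, byrow = TRUE)
  ibi <- suppressWarnings(as.numeric(m[, 2]))
  bad <- which(is.na(ibi) | ibi <= 0)
  if (length(bad))
    stop("parse error at line ", rowno[bad[1]], " of ", path,
         ": IBI must be a positive number, got '", m[bad[1], 2], "'")
  bt <- suppressWarnings(as.numeric(m[, 1]))
  if (anyNA(bt))
    stop("parse error at line ", rowno[which(is.na(bt))[1]], " of ", path,
         ": non-numeric beat_time_s")
  if (length(bt) > 1 && any(diff(bt) <= 0))
    stop("validation error in ", path, ": beat times not strictly increasing")
  flags <- apply(m[, 3:6, drop = FALSE], 2, function(v) {
    out <- suppressWarnings(as.integer(v))
    if (anyNA(out) || !all(out %in% 0:1))
      stop("parse error in ", path, ": flag columns must be 0/1")
    as.logical(out)
  })
  flags <- matrix(flags, ncol = 4)
  ibi_trace(ibi, beat_time_s = bt,
            corrected = flags[, 1], flat = flags[, 2],
            stair = flags[, 3], out_of_bounds = flags[, 4],
            activity = m[, 7],
            individual_id = meta$individual_id %||% "",
            tag_id = meta$tag_id %||% "",
            session_start = meta$session_start %||% NA_character_,
            covariates = cov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an IBI trace to the canonical text format
#'
#' The output round-trips through [read_trace()] bit-exactly: metadata as
#' `#key=value` comment lines, then a header row, then one beat per row with
#' flags serialised as 0/1.
#'
#' @param trace an [ibi_trace].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_ibi_trace(trace)
  b <- trace$beats
  meta <- character(0)
  if (nzchar(trace$individual_id))
    meta <- c(meta, paste0("#individual_id=", trace$individual_id))
  if (nzchar(trace$tag_id))
    meta <- c(meta, paste0("#tag_id=", trace$tag_id))
  if (!is.na(trace$session_start %||% NA))
    meta <- c(meta, paste0("#session_start=", trace$session_start))
  for (k in intersect(COVARIATE_NAMES, names(trace$covariates)))
    meta <- c(meta, paste0("#", k, "=",
                           format(trace$covariates[[k]], digits = 17)))
  header <- "beat_time_s,ibi_ms,corrected,flat,stair,out_of_bounds,activity"
  rows <- if (nrow(b)) {
    paste(format_num(b$beat_time_s), format_num(b$ibi_ms),
          as.integer(b$corrected), as.integer(b$flat), as.integer(b$stair),
          as.integer(b$out_of_bounds), b$activity, sep = ",")
  } else character(0)
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

# full-precision, locale-independent number formatting
format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                               trim = TRUE),
         character(1))
}

#' Read a per-second activity series
#'
#' Expects a comma-delimited file with header `second,label`, one row per
#' classified second.
#'
#' @param path file to read.
#' @return an [activity_series].
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || trimws(lines[1]) != "second,label")
    stop("parse error in ", path, ": expected header 'second,label'")
  rows <- lines[-1]
  if (!length(rows)) return(activity_series(integer(0), character(0)))
  parts <- strsplit(rows, ",", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("parse error in ", path, ": expected 2 fields per row")
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  sec <- suppressWarnings(as.integer(m[, 1]))
  if (anyNA(sec)) stop("parse error in ", path, ": non-integer second")
  lab <- trimws(m[, 2])
  bad <- which(!lab %in% c("Inactive", "Active"))
  if (length(bad))
    stop("parse error at line ", bad[1] + 1, " of ", path,
         ": unknown label '", lab[bad[1]], "'")
  activity_series(sec, lab)
}

#' Write a per-second activity series
#' @param activity an [activity_series].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_activity <- function(activity, path) {
  writeLines(c("second,label",
               paste(activity$second, activity$label, sep = ",")),
             path)
  invisible(path)
}
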