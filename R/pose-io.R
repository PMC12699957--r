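#' Read a pose stream
#'
#' Reads a time series of 10-landmark skeleton frames from disk. Two dialects
#' are supported:
#' \describe{
#'   \item{jsonl}{one frame per line:
#'     `{"t": <s>, "landmarks": {"head": [x,y,z], ...}, "conf": {...}}`
#'     with all 10 canonical landmarks required and `conf` optional.}
#'   \item{csv}{header `t,head_x,head_y,head_z,...,right_ankle_z`
#'     (31 columns), plus optional `conf_<landmark>` columns.}
#' }
#' Every frame is validated on the way in; a frame missing a landmark or
#' carrying a non-finite coordinate is a parse error naming the offending
#' line. Timestamps must be strictly increasing. The frame rate is inferred
#' from the median frame spacing unless `fps` is given.
#'
#' @param path Path to the file.
#' @param format `"jsonl"` or `"csv"`; default guesses from the file
#'   extension.
#' @param fps Optional nominal frames per second; inferred from timestamps
#'   when `NULL`.
#' @return A [motion_sequence()].
#' @seealso [write_pose_stream()]
#' @export
read_pose_stream <- function(path, format = c("auto", "jsonl", "csv"),
                             fps = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  frames <- switch(format,
    jsonl = read_frames_jsonl(path),
    csv = read_frames_csv(path))
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1L
    stop(sprintf("non-monotone timestamps: record %d (t=%.6f) does not advance",
                 bad, times[bad]), call. = FALSE)
  }
  if (is.null(fps)) {
    fps <- if (length(times) > 1L) 1 / stats::median(diff(times)) else 30
  }
  motion_sequence(frames, fps = fps, metadata = list(source = path))
}

read_frames_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  canon <- landmark_names()
  frames <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$t) || is.null(rec$landmarks)) {
      stop(sprintf("malformed JSONL record at line %d", i), call. = FALSE)
    }
    missing <- setdiff(canon, names(rec$landmarks))
    if (length(missing) > 0L) {
      stop(sprintf("line %d: missing landmark(s) %s", i,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    pos <- t(vapply(rec$landmarks[canon], as.numeric, numeric(3)))
    colnames(pos) <- c("x", "y", "z")
    conf <- if (!is.null(rec$conf)) unlist(rec$conf) else NULL
    frame <- structure(list(time = as.numeric(rec$t), positions = pos,
                            confidence = conf), class = "pose_frame")
    findings <- validate_frame(frame)
    if (length(findings) > 0L) {
      stop(sprintf("line %d: %s", i, paste(findings, collapse = "; ")),
           call. = FALSE)
    }
    frames[[i]] <- frame
  }
  frames
}

read_frames_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  canon <- landmark_names()
  want <- c("t", paste0(rep(canon, each = 3), "_", c("x", "y", "z")))
  missing <- setdiff(want, names(df))
  if (length(missing) > 0L) {
    stop("CSV pose stream missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  conf_cols <- intersect(paste0("conf_", canon), names(df))
  frames <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pos <- matrix(NA_real_, 10L, 3L, dimnames = list(canon, c("x", "y", "z")))
    for (lm in canon) {
      pos[lm, ] <- as.numeric(df[i, paste0(lm, "_", c("x", "y", "z"))])
    }
    conf <- NULL
    if (length(conf_cols) > 0L) {
      conf <- as.numeric(df[i, conf_cols])
      names(conf) <- sub("^conf_", "", conf_cols)
    }
    frame <- structure(list(time = df$t[i], positions = pos,
                            confidence = conf), class = "pose_frame")
    findings <- validate_frame(frame)
    if (length(findings) > 0L) {
      stop(sprintf("line %d: %s", i + 1L, paste(findings, collapse = "; ")),
           call. = FALSE)
    }
    frames[[i]] <- frame
  }
  frames
}

fmt6 <- function(x) sprintf("%.6f", x)

#' Write a pose stream
#'
#' Serializes a motion sequence in a canonical form — fixed landmark order and
#' fixed 6-decimal precision — so that write/read round-trips are
#' byte-stable. An empty sequence produces an empty JSONL file or a
#' header-only CSV.
#'
#' @param seq A [motion_sequence()].
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @return Invisibly, `path`.
#' @export
write_pose_stream <- function(seq, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  canon <- landmark_names()
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "jsonl") {
    for (f in seq$frames) {
      lms <- vapply(canon, function(lm) {
        sprintf("\"%s\":[%s]", lm, paste(fmt6(f$positions[lm, ]), collapse = ","))
      }, character(1))
      line <- sprintf("{\"t\":%s,\"landmarks\":{%s}", fmt6(f$time),
                      paste(lms, collapse = ","))
      if (!is.null(f$confidence)) {
        cf <- vapply(canon, function(lm) {
          sprintf("\"%s\":%s", lm, fmt6(f$confidence[[lm]]))
        }, character(1))
        line <- paste0(line, ",\"conf\":{", paste(cf, collapse = ","), "}")
      }
      writeLines(paste0(line, "}"), con)
    }
  } else {
    has_conf <- length(seq$frames) > 0L && !is.null(seq$frames[[1]]$confidence)
    header <- c("t", paste0(rep(canon, each = 3), "_", c("x", "y", "z")))
    if (has_conf) header <- c(header, paste0("conf_", canon))
    writeLines(paste(header, collapse = ","), con)
    for (f in seq$frames) {
      vals <- c(fmt6(f$time), fmt6(as.vector(t(f$positions[canon, ]))))
      if (has_conf) vals <- c(vals, fmt6(unlist(f$confidence[canon])))
      writeLines(paste(vals, collapse = ","), con)
    }
  }
  invisible(path)
}
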