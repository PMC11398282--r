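#' Write a landmark stream to disk
#'
#' CSV dialect: header `t,x0,y0,...,x67,y67,pxl,pyl,pxr,pyr,detector`, one
#' row per frame, empty fields for absent pupils. The JSON-lines dialect
#' (`.jsonl`) carries the same fields, one object per line.
#'
#' @param stream a `landmark_stream`.
#' @param path output path; format chosen by extension (`.csv` or
#'   `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_landmark_stream <- function(stream, path) {
  stopifnot(inherits(stream, "landmark_stream"))
  df <- stream_as_table(stream)
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, ])
      rec <- rec[!vapply(rec, function(v) is.na(v) && !is.character(v),
                         logical(1))]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

stream_as_table <- function(stream) {
  n <- length(stream$t)
  pts <- matrix(NA_real_, n, 136L)
  pts[, seq(1, 136, by = 2)] <- stream$points[, , 1]
  pts[, seq(2, 136, by = 2)] <- stream$points[, , 2]
  colnames(pts) <- paste0(rep(c("x", "y"), 68), rep(0:67, each = 2))
  df <- data.frame(t = stream$t, pts,
                   pxl = stream$pupil_left[, 1],
                   pyl = stream$pupil_left[, 2],
                   pxr = stream$pupil_right[, 1],
                   pyr = stream$pupil_right[, 2],
                   detector = stream$detector)
  df
}

#' Read a landmark stream
#'
#' Accepts the CSV dialect of [write_landmark_stream()] or its JSON-lines
#' equivalent. Pupil columns and the detector tag are optional; absent
#' detector tags default to `"gradient"`.
#'
#' @param path input path (`.csv` or `.jsonl`).
#' @return a `landmark_stream`.
#' @export
read_landmark_stream <- function(path) {
  df <- if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[i]),
               error = function(e) stop("malformed JSON at line ", i, ": ",
                                        conditionMessage(e)))
    })
    cols <- unique(unlist(lapply(recs, names)))
    as.data.frame(
      lapply(stats::setNames(cols, cols), function(cn) {
        vals <- lapply(recs, function(r) r[[cn]] %||% NA)
        if (cn == "detector") as.character(unlist(vals)) else
          as.numeric(unlist(vals))
      })
    )
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  table_as_stream(df)
}

table_as_stream <- function(df) {
  coord_cols <- paste0(rep(c("x", "y"), 68), rep(0:67, each = 2))
  missing <- setdiff(c("t", coord_cols), names(df))
  if (length(missing)) {
    stop("landmark stream is missing columns: ",
         paste(utils::head(missing, 4), collapse = ", "))
  }
  n <- nrow(df)
  pts <- array(NA_real_, dim = c(n, 68L, 2L))
  pts[, , 1] <- as.matrix(df[, paste0("x", 0:67)])
  pts[, , 2] <- as.matrix(df[, paste0("y", 0:67)])
  grab <- function(cn) if (cn %in% names(df)) as.numeric(df[[cn]]) else
    rep(NA_real_, n)
  det <- if ("detector" %in% names(df) &&
             !all(is.na(df$detector))) as.character(df$detector) else
    rep("gradient", n)
  det[is.na(det) | det == ""] <- "gradient"
  new_landmark_stream(
    t = as.numeric(df$t), points = pts,
    pupil_left = cbind(grab("pxl"), grab("pyl")),
    pupil_right = cbind(grab("pxr"), grab("pyr")),
    detector = det
  )
}
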