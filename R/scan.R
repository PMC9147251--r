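#' Tile a genome into overlapping chunks
#'
#' 1-based inclusive intervals of length `chunk_len` (the last interval may
#' be shorter), with consecutive intervals sharing exactly `overlap`
#' positions; the union covers position 1 through the sequence length.
#'
#' @param seq an `mm_sequence`, or an integer sequence length.
#' @param chunk_len chunk length (`> overlap`).
#' @param overlap shared positions between consecutive chunks (`>= 0`).
#' @return A tibble with `chunk`, `start`, `end`.
#' @export
chunk_genome <- function(seq, chunk_len, overlap = 0L) {
  L <- if (inherits(seq, "mm_sequence")) length(seq) else as.integer(seq)
  stopifnot(L >= 1, chunk_len > overlap, overlap >= 0)
  if (chunk_len >= L) return(tibble(chunk = 1L, start = 1L, end = L))
  starts <- seq(1L, L, by = chunk_len - overlap)
  ends <- pmin(starts + chunk_len - 1L, L)
  keep <- c(TRUE, ends[-length(ends)] < L)
  starts <- starts[keep]; ends <- ends[keep]
  tibble(chunk = seq_along(starts), start = as.integer(starts),
         end = as.integer(ends))
}

#' Chunked homology scan of a query against a long subject
#'
#' Tiles the subject into chunks (overlapping by `overlap`, default
#' `frame_len` so no candidate frame is lost at a seam), and runs
#' [find_top_frames()] of the query against every chunk.  The chunk-level
#' run spectrum is that of the best frame in the chunk, mirroring segment-wise
#' histograms of micro-modular identities.  Chunks are independent
#' computations, so results do not depend on their order.
#'
#' @param query,subject `mm_sequence` (nucleotide).
#' @param scheme an [scoring_scheme()].
#' @param chunk_len,overlap subject tiling (defaults 50,000 / `frame_len`).
#' @param frame_len,step,top_k frame scan parameters (see
#'   [find_top_frames()]).
#' @param progress log per-chunk progress to standard error.
#' @return An `mm_scan`: tibble `segments` with `chunk`, `start`, `end`,
#'   `best_identity`, a `frames` list-column (per-chunk frame table with
#'   subject coordinates) and a `spectrum` list-column.
#' @export
scan_genome <- function(query, subject, scheme = scoring_scheme(),
                        chunk_len = 50000L, overlap = NULL,
                        frame_len = 550L, step = 25L, top_k = 3L,
                        progress = FALSE) {
  query <- as_mm_sequence(query); subject <- as_mm_sequence(subject)
  if (is.null(overlap)) overlap <- min(frame_len, chunk_len - 1L)
  chunks <- chunk_genome(subject, chunk_len, overlap)
  rows <- purrr::pmap(chunks, function(chunk, start, end) {
    if (progress)
      message(sprintf("[%s] chunk %d: %d-%d", format(Sys.time(), "%H:%M:%S"),
                      chunk, start, end))
    sub <- subsequence(subject, start, end)
    fr <- find_top_frames(query, sub, scheme, frame_len = frame_len,
                          step = step, top_k = top_k)
    fr$b_start <- fr$b_start + start - 1L
    fr$b_end <- fr$b_end + start - 1L
    tibble(chunk = chunk, start = start, end = end,
           best_identity = fr$identity_percent[1],
           frames = list(fr), spectrum = list(fr$spectrum[[1]]))
  })
  structure(list(segments = dplyr::bind_rows(rows),
                 chunk_len = as.integer(chunk_len),
                 overlap = as.integer(overlap),
                 frame_len = as.integer(frame_len), step = as.integer(step),
                 query_id = query$id, subject_id = subject$id),
            class = "mm_scan")
}

#' @export
print.mm_scan <- function(x, ...) {
  cat(sprintf("<mm_scan> %s vs %s: %d chunks of %d (overlap %d)\n",
              x$query_id, x$subject_id, nrow(x$segments), x$chunk_len,
              x$overlap))
  print(dplyr::select(x$segments, "chunk", "start", "end", "best_identity"))
  invisible(x)
}

#' Long-format histogram table of a scan
#'
#' One row per segment and run-length bin, ready for bar plots; percentages
#' per segment sum to 100 (via [spectrum_percentages()]).
#'
#' @param result an `mm_scan`.
#' @param min_n smallest run length included (default 3).
#' @return A tibble with `segment`, `start`, `end`, `k`, `count`, `percent`.
#' @export
histogram_report <- function(result, min_n = 3L) {
  stopifnot(inherits(result, "mm_scan"), nrow(result$segments) > 0)
  purrr::pmap(result$segments, function(chunk, start, end, spectrum, ...) {
    dplyr::mutate(spectrum_percentages(spectrum, min_n = min_n),
                  segment = chunk, start = start, end = end,
                  .before = 1)
  }) |> dplyr::bind_rows()
}
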