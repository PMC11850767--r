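# CSV/JSON interchange: UTF-8, comma-separated, header row, '.' decimal.

#' Write / read a pose session as long-format CSV
#'
#' Columns: frame, animal, node, x, y.
#'
#' @param session A `pose_session`. @param path File path.
#' @return `read_pose_csv` returns a `pose_session` (without labels).
#' @export
write_pose_csv <- function(session, path) {
  co <- session$coords
  dn <- dimnames(co)
  rows <- expand.grid(frame = seq_len(dim(co)[1]), animal = dn[[2]],
                      node = dn[[3]], stringsAsFactors = FALSE)
  rows$x <- as.numeric(co[cbind(rows$frame, match(rows$animal, dn[[2]]),
                                match(rows$node, dn[[3]]), 1)])
  rows$y <- as.numeric(co[cbind(rows$frame, match(rows$animal, dn[[2]]),
                                match(rows$node, dn[[3]]), 2)])
  rows <- rows[order(rows$frame, rows$animal, rows$node), ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @param fps Frame rate to attach on read (default 30).
#' @export
read_pose_csv <- function(path, fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "animal", "node", "x", "y")
  if (!all(need %in% names(df))) {
    stop("pose CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) stop("non-finite coordinate at row ", bad[1] + 1L)
  animals <- sort(unique(df$animal))
  nodes <- pose_nodes[pose_nodes %in% unique(df$node)]
  frames <- sort(unique(df$frame))
  co <- array(NA_real_, c(length(frames), length(animals), length(nodes), 2),
              dimnames = list(NULL, animals, nodes, c("x", "y")))
  co[cbind(match(df$frame, frames), match(df$animal, animals),
           match(df$node, nodes), 1)] <- df$x
  co[cbind(match(df$frame, frames), match(df$animal, animals),
           match(df$node, nodes), 2)] <- df$y
  structure(list(fps = fps, frames = length(frames), coords = co,
                 labels = NULL), class = "pose_session")
}

#' Write / read spike times as CSV (columns: unit, t_s)
#'
#' @param spikes Named list of spike-time vectors (names = unit ids).
#' @param path File path.
#' @return `read_spikes_csv` returns the named list.
#' @export
write_spikes_csv <- function(spikes, path) {
  df <- do.call(rbind, lapply(names(spikes), function(u) {
    data.frame(unit = u, t_s = spikes[[u]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit", "t_s") %in% names(df))) {
    stop("spike CSV must have columns: unit, t_s")
  }
  split(df$t_s, df$unit)
}

#' Write / read a rate matrix as CSV (units x bins)
#'
#' @param rates N x T matrix. @param path File path.
#' @return `read_rates_csv` returns the matrix.
#' @export
write_rates_csv <- function(rates, path) {
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write an analysis report as JSON
#'
#' @param report A list of results (numbers, vectors, tables).
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
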