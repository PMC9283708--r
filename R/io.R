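#' Write a cell-configuration snapshot to CSV
#'
#' Plain CSV with header `cell_id,x,y`, positions in cell-diameter units,
#' written at full double precision so a write/read round trip is
#' lossless.  Metadata (package version, time stamp) is carried in `#`
#' comment lines before the header.
#'
#' @param config a [cell_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(config, path) {
  stopifnot(inherits(config, "cell_config"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# tumornet %s snapshot",
            as.character(utils::packageVersion("tumornet"))),
    sprintf("# time=%.17g n=%d", config$time, nrow(config$pos)),
    "cell_id,x,y"), con)
  if (nrow(config$pos) > 0)
    writeLines(sprintf("%d,%.17g,%.17g", config$ids,
                       config$pos[, 1], config$pos[, 2]), con)
  invisible(path)
}

#' Read a cell-configuration snapshot from CSV
#'
#' Accepts LF or CRLF line endings and `#` comment lines; requires the
#' exact header `cell_id,x,y`, unique ids and finite coordinates.
#'
#' @param path input file.
#' @param time time stamp to attach (default taken from a `# time=` header
#'   comment when present, else 0).
#' @return A [cell_config()].
#' @export
read_snapshot <- function(path, time = NULL) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (is.null(time)) {
    tm <- grep("^# time=", lines, value = TRUE)
    time <- if (length(tm))
      as.numeric(sub("^# time=([^ ]+).*$", "\\1", tm[1])) else 0
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) == 0) stop("snapshot file has no header line")
  header_line <- body_idx[1]
  if (trimws(lines[header_line]) != "cell_id,x,y")
    stop(sprintf("line %d: expected header 'cell_id,x,y', got '%s'",
                 header_line, lines[header_line]))
  data_idx <- body_idx[-1]
  if (length(data_idx) == 0)
    return(cell_config(numeric(0), numeric(0), ids = integer(0), time = time))
  fields <- strsplit(lines[data_idx], ",", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad))
    stop(sprintf("line %d: expected 3 comma-separated fields",
                 data_idx[bad[1]]))
  m <- matrix(unlist(fields), ncol = 3, byrow = TRUE)
  ids <- suppressWarnings(as.integer(m[, 1]))
  xs <- suppressWarnings(as.numeric(m[, 2]))
  ys <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(ids) | !is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop(sprintf("line %d: non-numeric or non-finite snapshot record '%s'",
                 data_idx[bad[1]], lines[data_idx[bad[1]]]))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate cell_id in snapshot: %s",
                 paste(unique(dup), collapse = ", ")))
  cell_config(xs, ys, ids = ids, time = time)
}

#' Write a contact network as an edge-list TSV
#'
#' One undirected edge per line as `node_i<TAB>node_j` with `i < j`, using
#' the original cell ids.
#'
#' @param net a [contact_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "contact_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tumornet edge list: %d nodes, %d links, threshold %g",
                     net$n_nodes, net$n_links, net$threshold), con)
  if (net$n_links > 0) {
    a <- net$node_ids[net$edges[, 1]]
    b <- net$node_ids[net$edges[, 2]]
    writeLines(sprintf("%d\t%d", pmin(a, b), pmax(a, b)), con)
  }
  invisible(path)
}

#' Write a network summary as flat JSON
#'
#' @param x a `network_summary` (see [summary.contact_network()]) or a
#'   plain list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_summary <- function(x, path) {
  out <- unclass(x)
  out$degree_dist <- as.list(out$degree_dist)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Parameters, seed, extinct flag and final population of a simulation
#' run; the sidecar record of a snapshot CSV.
#'
#' @param run a `tumor_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(run, path) {
  stopifnot(inherits(run, "tumor_run"))
  jsonlite::write_json(
    list(package = "tumornet",
         version = as.character(utils::packageVersion("tumornet")),
         params = unclass(run$params),
         extinct = run$extinct,
         final_n = nrow(run$final$pos),
         t_end = max(run$population$time)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a sweep curve as tidy CSV
#'
#' @param curve a [run_sweep()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(curve, path) {
  stopifnot(inherits(curve, "sweep_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
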