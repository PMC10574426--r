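#' Read and write GMT gene-set files
#'
#' Tab-separated gene-set format: one term per line as
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. The category of
#' a term (`KEGG`, `BP`, `CC`, `MF`) is encoded as a `category:name` prefix
#' in the description field by [write_gmt()] and recovered by
#' [read_gmt()]; descriptions without a recognized prefix default to
#' `KEGG`.
#'
#' @param path File to read or write.
#' @return `read_gmt()`: a gene-set collection tibble (`term_id`,
#'   `term_name`, `category`, `genes` list-column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- map(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (fewer than 3 fields)")
    desc <- parts[2]
    m <- regmatches(desc, regexec("^(KEGG|BP|CC|MF):(.*)$", desc))[[1]]
    if (length(m) == 3) {
      category <- m[2]; name <- m[3]
    } else {
      category <- "KEGG"; name <- desc
    }
    tibble(term_id = parts[1], term_name = name, category = category,
           genes = list(parts[-(1:2)]))
  })
  bind_rows(rows)
}

#' @rdname read_gmt
#' @param collection A gene-set collection tibble.
#' @export
write_gmt <- function(collection, path) {
  check_columns(collection, c("term_id", "term_name", "category", "genes"),
                "gene-set collection")
  lines <- purrr::pmap_chr(
    list(collection$term_id, collection$term_name, collection$category,
         collection$genes),
    function(id, nm, cat, members) {
      paste(c(id, paste0(cat, ":", nm), members), collapse = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column XVG-dialect series
#'
#' Reads the plotting format produced by MD analysis tools: lines starting
#' with `@`, `#` or `&` are headers and are skipped; data lines carry a
#' time and a value column. Time is converted to ns when given in ps.
#'
#' @param path File to read.
#' @param time_unit Unit of the file's time column (`"ns"` or `"ps"`).
#' @param label Complex identifier for the series.
#' @return A [trajectory_series()].
#' @export
read_xvg <- function(path, time_unit = c("ns", "ps"), label = NULL) {
  time_unit <- match.arg(time_unit)
  lines <- readLines(path, warn = FALSE)
  data <- lines[!grepl("^\\s*[@#&]", lines) & nzchar(trimws(lines))]
  if (length(data) == 0) abort("no data lines in XVG file")
  fields <- strsplit(trimws(data), "\\s+")
  if (any(lengths(fields) < 2)) abort("XVG data lines need two columns")
  time <- as.numeric(map_chr(fields, 1))
  value <- as.numeric(map_chr(fields, 2))
  if (any(is.na(time)) || any(is.na(value))) abort("non-numeric XVG data")
  if (time_unit == "ps") time <- time / 1000
  trajectory_series(time, value,
                    label = label %||% tools::file_path_sans_ext(basename(path)))
}

#' Read a STRING-style edge export and build the filtered graph
#'
#' Convenience wrapper: reads the tab-separated edge table (`node1`,
#' `node2`, `combined_score`) and applies [graph_from_string_edges()].
#'
#' @param path TSV file.
#' @inheritParams graph_from_string_edges
#' @return An `igraph` object.
#' @export
read_string_edges <- function(path, min_score = 0.9, nodes = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  graph_from_string_edges(tbl, min_score = min_score, nodes = nodes)
}
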