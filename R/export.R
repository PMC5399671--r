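#' Export a network to SIF, GraphML or JSON
#'
#' SIF writes one interaction per line, `source activates|represses target`
#' (displayed edges only). GraphML carries every node and edge attribute,
#' including withdrawn edges with their flag. JSON serializes the full object
#' losslessly, so `import_network(export_network(n)) == n`.
#'
#' @param network An `otog_network`.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"json"` (default: from the file
#'   extension).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("auto", "sif", "graphml", "json")) {
  stopifnot(inherits(network, "otog_network"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", json = "json",
                     abort(sprintf("unknown network format `%s`", ext)))
  }
  if (nrow(network$edges) &&
      any(network$edges$provenance == "" | is.na(network$edges$provenance))) {
    abort("every exported edge must carry at least one provenance entry")
  }
  switch(format,
    sif = {
      disp <- network$edges[!network$edges$removed_by_parsimony, ]
      lines <- sprintf("%s %s %s", disp$source,
                       ifelse(disp$sign == 1L, "activates", "represses"),
                       disp$target)
      writeLines(lines, path)
    },
    graphml = {
      g <- network_igraph(network)
      igraph::write_graph(g, path, format = "graphml")
    },
    json = {
      payload <- list(
        nodes = network$nodes, edges = network$edges,
        gates = network$gates, ambiguities = network$ambiguities
      )
      jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                           null = "null", na = "null", pretty = TRUE)
    }
  )
  invisible(path)
}

# igraph view with all attributes (used for GraphML export and plotting)
network_igraph <- function(network) {
  nodes <- network$nodes |>
    mutate(stage_of_onset = ifelse(is.na(.data$stage_of_onset), "unassigned",
                                   .data$stage_of_onset))
  edges <- network$edges
  igraph::graph_from_data_frame(
    as.data.frame(edges), directed = TRUE,
    vertices = as.data.frame(nodes |> rename(name = "gene")))
}

#' Import a JSON network written by [export_network()]
#'
#' @param path JSON file path.
#' @return The reconstructed `otog_network`.
#' @export
import_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_tbl <- function(x, template) {
    if (length(x) == 0 || (is.list(x) && length(x[[1]]) == 0)) return(template)
    as_tibble(lapply(x, unlist))
  }
  edges <- to_tbl(raw$edges, tibble(
    source = character(), target = character(), sign = integer(),
    evidence = character(), provenance = character(), direct = logical(),
    removed_by_parsimony = logical()))
  if (nrow(edges)) {
    edges <- edges |> mutate(sign = as.integer(.data$sign),
                             direct = as.logical(.data$direct),
                             removed_by_parsimony = as.logical(.data$removed_by_parsimony))
  }
  nodes <- to_tbl(raw$nodes, tibble(gene = character(),
                                    stage_of_onset = character(),
                                    region = character()))
  if (nrow(nodes) && !"stage_of_onset" %in% names(nodes)) {
    nodes$stage_of_onset <- NA_character_
  }
  gates <- to_tbl(raw$gates, tibble(gene = character(), gate = character()))
  amb <- to_tbl(raw$ambiguities, tibble(
    a = character(), b = character(), target = character(),
    sign = integer(), note = character()))
  if (nrow(amb)) amb <- amb |> mutate(sign = as.integer(.data$sign))
  assemble_network(edges, nodes = nodes, gates = gates, ambiguities = amb)
}

#' Read and write expression matrices as TSV with a metadata sidecar
#'
#' The matrix TSV has genes as rows and a header of sample ids; the sidecar
#' TSV carries `sample_id`, `stage`, `condition`, `replicate`.
#'
#' @param x An [expr_matrix()].
#' @param path Matrix TSV path; the sidecar is `<path>.meta.tsv` unless given.
#' @param meta_path Optional explicit sidecar path.
#' @return `write_expr()`: `path` invisibly; `read_expr()`: an
#'   [expr_matrix()].
#' @export
write_expr <- function(x, path, meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(x, "otog_expr"))
  readr::write_tsv(x$values, path)
  readr::write_tsv(x$meta, meta_path)
  if (!is.null(x$rpkm)) {
    readr::write_tsv(x$rpkm, paste0(tools::file_path_sans_ext(path), ".rpkm.tsv"))
  }
  invisible(path)
}

#' @rdname write_expr
#' @param value_kind,assay Passed to [expr_matrix()] on read.
#' @export
read_expr <- function(path, meta_path = paste0(path, ".meta.tsv"),
                      value_kind = "counts", assay = "generic") {
  values <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  rpkm_path <- paste0(tools::file_path_sans_ext(path), ".rpkm.tsv")
  rpkm <- if (file.exists(rpkm_path)) {
    readr::read_tsv(rpkm_path, show_col_types = FALSE)
  }
  expr_matrix(values, meta, value_kind = value_kind, assay = assay, rpkm = rpkm)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}

#' Read a curated literature edge table
#'
#' CSV schema: `source,target,sign,direct,citation`.
#'
#' @param path CSV path.
#' @return Tibble suitable for [merge_literature()].
#' @export
read_curated_edges <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    source = readr::col_character(),
                    target = readr::col_character(),
                    sign = readr::col_integer(),
                    direct = readr::col_logical(),
                    citation = readr::col_character()))
}
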