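#' Construct a connectome from neuron and edge tables
#'
#' A connectome is a neuron table plus a synapse-count edge list. Duplicate
#' `(pre_id, post_id)` rows are summed into a single edge; missing or
#' unrecognised neuron classes become `"other"` and missing transmitter
#' predictions become `"unknown"`.
#'
#' @param neurons Data frame with columns `neuron_id`, `cell_type`, `class`
#'   and optionally `predicted_nt`.
#' @param edges Data frame with columns `pre_id`, `post_id`, `synapse_count`.
#' @param metadata Optional list of provenance (e.g. planted ground truth).
#'
#' @return An object of class `connectome`: a list with tibbles `neurons`
#'   and `edges`, and `metadata`.
#' @export
connectome <- function(neurons, edges, metadata = NULL) {
  neurons <- as_tibble(neurons)
  edges <- as_tibble(edges)

  req_n <- c("neuron_id", "cell_type", "class")
  if (!all(req_n %in% names(neurons))) {
    abort(paste0("neuron table must have columns: ", paste(req_n, collapse = ", ")),
          class = "mblearn_schema_error")
  }
  req_e <- c("pre_id", "post_id", "synapse_count")
  if (!all(req_e %in% names(edges))) {
    abort(paste0("edge table must have columns: ", paste(req_e, collapse = ", ")),
          class = "mblearn_schema_error")
  }
  neurons$neuron_id <- as.character(neurons$neuron_id)
  if (anyDuplicated(neurons$neuron_id)) {
    abort("neuron_id values must be unique", class = "mblearn_schema_error")
  }
  if (!"predicted_nt" %in% names(neurons)) neurons$predicted_nt <- "unknown"
  neurons <- neurons |>
    dplyr::mutate(
      class = ifelse(is.na(.data$class) | !(.data$class %in% NEURON_CLASSES),
                     "other", .data$class),
      predicted_nt = ifelse(is.na(.data$predicted_nt) |
                              !(.data$predicted_nt %in% NT_LEVELS),
                            "unknown", .data$predicted_nt))

  edges$pre_id <- as.character(edges$pre_id)
  edges$post_id <- as.character(edges$post_id)
  bad_count <- !is.finite(edges$synapse_count) |
    edges$synapse_count != round(edges$synapse_count) | edges$synapse_count <= 0
  if (any(bad_count)) {
    abort(paste0("synapse_count must be a positive integer; offending row(s): ",
                 paste(utils::head(which(bad_count), 5), collapse = ", ")),
          class = "mblearn_schema_error")
  }
  missing_end <- !(edges$pre_id %in% neurons$neuron_id) |
    !(edges$post_id %in% neurons$neuron_id)
  if (any(missing_end)) {
    i <- which(missing_end)[1]
    abort(sprintf("edge row %d (%s -> %s) references a neuron_id absent from the neuron table",
                  i, edges$pre_id[i], edges$post_id[i]),
          class = "mblearn_schema_error")
  }
  edges <- edges |>
    dplyr::summarise(synapse_count = sum(.data$synapse_count),
                     .by = c("pre_id", "post_id")) |>
    dplyr::mutate(synapse_count = as.integer(.data$synapse_count))

  structure(list(neurons = neurons, edges = edges, metadata = metadata),
            class = "connectome")
}

#' Load a connectome from neuPrint-style CSV exports
#'
#' Reads a neuron table (`neuron_id,cell_type,class,predicted_nt`) and an
#' edge list (`pre_id,post_id,synapse_count`), validates both, sums duplicate
#' directed edges, and reports how many neurons and edges were loaded.
#'
#' @param neurons_path,edges_path Paths to the two CSV files.
#' @return A [connectome()] object.
#' @export
load_connectome <- function(neurons_path, edges_path) {
  for (p in c(neurons_path, edges_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p),
                               class = "mblearn_schema_error")
  }
  neurons <- readr::read_csv(neurons_path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  edges <- readr::read_csv(edges_path, show_col_types = FALSE,
                           col_types = readr::cols(
                             pre_id = "c", post_id = "c",
                             synapse_count = "d"))
  cn <- connectome(neurons, edges)
  message(sprintf("Loaded %d neurons and %d edges (after merging duplicates)",
                  nrow(cn$neurons), nrow(cn$edges)))
  cn
}

#' @export
print.connectome <- function(x, ...) {
  cls <- table(x$neurons$class)
  cat("<connectome>", nrow(x$neurons), "neurons,", nrow(x$edges), "edges\n")
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$metadata$hub_cell_type)) {
    cat("  planted hub:", x$metadata$hub_cell_type, "\n")
  }
  invisible(x)
}

#' Write a connectome to the CSV dialect read by [load_connectome()]
#'
#' @param cn A [connectome()] object.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; writes `<stem>_neurons.csv`,
#'   `<stem>_edges.csv` and, when metadata is present, `<stem>_meta.json`.
#' @return Invisibly, the paths written.
#' @export
write_connectome <- function(cn, dir, stem = "connectome") {
  stopifnot(inherits(cn, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stem, c("_neurons.csv", "_edges.csv")))
  readr::write_csv(cn$neurons, paths[1])
  readr::write_csv(cn$edges, paths[2])
  if (!is.null(cn$metadata)) {
    mp <- file.path(dir, paste0(stem, "_meta.json"))
    jsonlite::write_json(cn$metadata, mp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, mp)
  }
  invisible(paths)
}

# Edge list aggregated to cell-type level: one row per (pre_type, post_type)
# with summed counts, plus the pre type's class and modal transmitter.
type_edges <- function(cn) {
  key <- cn$neurons |>
    dplyr::select("neuron_id", "cell_type", "class")
  cn$edges |>
    dplyr::inner_join(key, by = c(pre_id = "neuron_id")) |>
    dplyr::rename(pre_type = "cell_type", pre_class = "class") |>
    dplyr::inner_join(key, by = c(post_id = "neuron_id")) |>
    dplyr::rename(post_type = "cell_type", post_class = "class") |>
    dplyr::summarise(synapse_count = sum(.data$synapse_count),
                     .by = c("pre_type", "post_type", "pre_class", "post_class")) |>
    dplyr::left_join(type_nt(cn), by = c(pre_type = "cell_type")) |>
    dplyr::rename(pre_nt = "predicted_nt")
}

# Modal predicted transmitter per cell type (ties broken alphabetically).
type_nt <- function(cn) {
  cn$neurons |>
    dplyr::count(.data$cell_type, .data$predicted_nt) |>
    dplyr::arrange(.data$cell_type, dplyr::desc(.data$n), .data$predicted_nt) |>
    dplyr::distinct(.data$cell_type, .keep_all = TRUE) |>
    dplyr::select("cell_type", "predicted_nt")
}

# Map cell_type -> class (modal; generator and hemibrain types are uniform).
type_class <- function(cn) {
  cn$neurons |>
    dplyr::count(.data$cell_type, .data$class) |>
    dplyr::arrange(.data$cell_type, dplyr::desc(.data$n), .data$class) |>
    dplyr::distinct(.data$cell_type, .keep_all = TRUE) |>
    dplyr::select("cell_type", "class")
}
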