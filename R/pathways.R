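#' Screen interneuron cell types by total synapses with MBONs and DANs
#'
#' Reproduces the candidate-interneuron screen: an interneuron cell type is
#' retained when the synapses it exchanges with the given MBON and DAN cell
#' types -- inputs received from them plus outputs sent to them, summed over
#' all member neurons -- reach `min_total` (inclusive). MBONs, DANs and KCs
#' are never candidates themselves.
#'
#' @param cn A [connectome()].
#' @param mbon_set,dan_set Non-empty, disjoint character vectors of MBON and
#'   DAN cell types. Defaults: every cell type of class `MBON` / `DAN`.
#' @param min_total Inclusive screening threshold (default 100).
#' @return A tibble with one row per retained cell type: `cell_type`,
#'   `synapses_in` (received from the sets), `synapses_out` (sent to them)
#'   and `total`, sorted by `total` descending.
#' @export
core_interneurons <- function(cn, mbon_set = NULL, dan_set = NULL,
                              min_total = 100L) {
  stopifnot(inherits(cn, "connectome"))
  tc <- type_class(cn)
  if (is.null(mbon_set)) mbon_set <- tc$cell_type[tc$class == "MBON"]
  if (is.null(dan_set)) dan_set <- tc$cell_type[tc$class == "DAN"]
  if (length(mbon_set) == 0 || length(dan_set) == 0) {
    abort("mbon_set and dan_set must be non-empty",
          class = "mblearn_argument_error")
  }
  if (length(intersect(mbon_set, dan_set)) > 0) {
    abort("mbon_set and dan_set must be disjoint",
          class = "mblearn_argument_error")
  }
  partner <- c(mbon_set, dan_set)
  te <- type_edges(cn)
  eligible <- tc$cell_type[!tc$class %in% c("MBON", "DAN", "KC")]

  inputs <- te |>
    dplyr::filter(.data$pre_type %in% partner,
                  .data$post_type %in% eligible) |>
    dplyr::summarise(synapses_in = sum(.data$synapse_count),
                     .by = "post_type") |>
    dplyr::rename(cell_type = "post_type")
  outputs <- te |>
    dplyr::filter(.data$post_type %in% partner,
                  .data$pre_type %in% eligible) |>
    dplyr::summarise(synapses_out = sum(.data$synapse_count),
                     .by = "pre_type") |>
    dplyr::rename(cell_type = "pre_type")
  dplyr::full_join(inputs, outputs, by = "cell_type") |>
    dplyr::mutate(dplyr::across(c("synapses_in", "synapses_out"),
                                ~ tidyr::replace_na(.x, 0L)),
                  total = .data$synapses_in + .data$synapses_out) |>
    dplyr::filter(.data$total >= min_total) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$cell_type)
}

#' Scalar strength of a pathway from its per-hop synapse counts
#'
#' `min_hop` (default) is the bottleneck count, the minimum over hops;
#' `geometric_mean` is the geometric mean of the hop counts. Parallel
#' pathways between the same endpoints aggregate by summing per-path
#' strengths (see [enumerate_pathways()] output, or sum `strength` grouped
#' by endpoints).
#'
#' @param counts Numeric vector of per-hop synapse counts.
#' @param rule `"min_hop"` or `"geometric_mean"`.
#' @return A non-negative scalar.
#' @examples
#' pathway_strength(c(30, 20))                      # 20
#' pathway_strength(c(30, 20), "geometric_mean")    # sqrt(600)
#' @export
pathway_strength <- function(counts, rule = c("min_hop", "geometric_mean")) {
  rule <- match.arg(rule)
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(counts < 0)) {
    abort("counts must be a non-empty non-negative vector",
          class = "mblearn_argument_error")
  }
  switch(rule,
         min_hop = min(counts),
         geometric_mean = exp(mean(log(counts))))
}

#' Enumerate feedforward pathways from a source MBON to target DANs
#'
#' Finds every simple path `source -> [0..max_interneurons interneurons] ->
#' target` at the cell-type level (member-neuron counts summed per directed
#' type pair) whose every hop carries at least `min_edge_count` synapses.
#' Intermediate nodes are restricted to non-MBON/DAN/KC cell types; no node
#' repeats within a path. Each hop is annotated with the presynaptic type's
#' predicted transmitter.
#'
#' @param cn A [connectome()].
#' @param source Source cell type (e.g. the alpha1 output neuron's type).
#' @param targets Non-empty character vector of target DAN cell types.
#' @param max_interneurons Maximum interneurons between source and target:
#'   0, 1 or 2 (direct, one-hop, two-hop pathways).
#' @param min_edge_count Minimum per-hop synapse count (default 1).
#' @param rule Strength rule passed to [pathway_strength()].
#' @return A tibble with one row per pathway: `source`, `via1`, `via2`
#'   (`NA` when unused), `target`, `n_hops`, list-columns `counts` and
#'   `nts`, and `strength`; sorted by strength descending, ties broken
#'   lexicographically by node sequence.
#' @export
enumerate_pathways <- function(cn, source, targets, max_interneurons = 2L,
                               min_edge_count = 1L,
                               rule = c("min_hop", "geometric_mean")) {
  stopifnot(inherits(cn, "connectome"))
  rule <- match.arg(rule)
  if (length(targets) == 0) {
    abort("targets must be non-empty", class = "mblearn_argument_error")
  }
  if (!max_interneurons %in% 0:2) {
    abort("max_interneurons must be 0, 1 or 2", class = "mblearn_argument_error")
  }
  tc <- type_class(cn)
  if (!source %in% tc$cell_type) {
    abort(paste0("source cell type not present: ", source),
          class = "mblearn_argument_error")
  }
  te <- type_edges(cn) |>
    dplyr::filter(.data$synapse_count >= min_edge_count)
  nts <- type_nt(cn)
  nt_of <- stats::setNames(nts$predicted_nt, nts$cell_type)
  inter <- tc$cell_type[!tc$class %in% c("MBON", "DAN", "KC")]

  # adjacency: named list pre_type -> tibble(post_type, synapse_count)
  adj <- split(te[c("post_type", "synapse_count")], te$pre_type)
  succ <- function(v) adj[[v]] %||% tibble(post_type = character(),
                                           synapse_count = integer())

  paths <- list()
  add_path <- function(nodes, counts) {
    paths[[length(paths) + 1]] <<- list(nodes = nodes, counts = counts)
  }
  walk <- function(nodes, counts) {
    v <- nodes[length(nodes)]
    nxt <- succ(v)
    for (i in seq_len(nrow(nxt))) {
      u <- nxt$post_type[i]
      if (u %in% nodes) next
      cnt <- nxt$synapse_count[i]
      if (u %in% targets) add_path(c(nodes, u), c(counts, cnt))
      n_inter <- length(nodes)  # nodes beyond the source so far
      if (u %in% inter && n_inter <= max_interneurons) {
        walk(c(nodes, u), c(counts, cnt))
      }
    }
  }
  walk(source, integer())

  if (length(paths) == 0) {
    return(tibble(source = character(), via1 = character(),
                  via2 = character(), target = character(),
                  n_hops = integer(), counts = list(), nts = list(),
                  strength = numeric()))
  }
  out <- purrr::map_dfr(paths, function(p) {
    inter_nodes <- p$nodes[-c(1, length(p$nodes))]
    tibble(source = p$nodes[1],
           via1 = if (length(inter_nodes) >= 1) inter_nodes[1] else NA_character_,
           via2 = if (length(inter_nodes) >= 2) inter_nodes[2] else NA_character_,
           target = p$nodes[length(p$nodes)],
           n_hops = length(p$counts),
           counts = list(as.integer(p$counts)),
           nts = list(unname(nt_of[p$nodes[-length(p$nodes)]])),
           strength = pathway_strength(p$counts, rule))
  })
  seq_key <- paste(out$source, tidyr::replace_na(out$via1, ""),
                   tidyr::replace_na(out$via2, ""), out$target)
  out[order(-out$strength, seq_key), ]
}

#' Write enumerated pathways to CSV plus a JSON summary
#'
#' Flattens the list-columns of [enumerate_pathways()] output into
#' `;`-separated strings and writes a sidecar JSON with per-endpoint
#' aggregate strengths.
#'
#' @param pathways Output of [enumerate_pathways()].
#' @param csv_path Output CSV path; the JSON summary is written next to it
#'   with extension `.json`.
#' @return Invisibly, the paths written.
#' @export
write_pathways <- function(pathways, csv_path) {
  flat <- pathways |>
    dplyr::mutate(counts = purrr::map_chr(.data$counts, paste, collapse = ";"),
                  nts = purrr::map_chr(.data$nts, paste, collapse = ";"))
  readr::write_csv(flat, csv_path)
  agg <- pathways |>
    dplyr::summarise(n_paths = dplyr::n(),
                     aggregate_strength = sum(.data$strength),
                     .by = c("source", "target"))
  json_path <- sub("\\.csv$", ".json", csv_path)
  jsonlite::write_json(
    list(n_pathways = nrow(pathways), endpoint_summary = agg),
    json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' Input/output scatter of candidate interneurons
#'
#' For each candidate cell type, counts synapses received from the source
#' MBON type (`x`) and sent to the target DAN types (`y`), flagging the top
#' quantile of the `x * y` product as outliers -- the convention used to
#' spot hub interneurons that both read the teacher compartment's output
#' and drive the reward DANs.
#'
#' @param cn A [connectome()].
#' @param source_mbon Source MBON cell type(s) for the x axis.
#' @param target_dans Target DAN cell types for the y axis.
#' @param candidates Output of [core_interneurons()] (or any tibble with a
#'   `cell_type` column); must be non-empty.
#' @param outlier_quantile Product quantile above which rows are flagged
#'   (default 0.99, the top 1%).
#' @return A tibble `cell_type`, `x`, `y`, `product`, `outlier`.
#' @export
input_output_scatter <- function(cn, source_mbon, target_dans, candidates,
                                 outlier_quantile = 0.99) {
  stopifnot(inherits(cn, "connectome"))
  if (nrow(candidates) == 0) {
    abort("candidates must be non-empty", class = "mblearn_argument_error")
  }
  te <- type_edges(cn)
  x_tab <- te |>
    dplyr::filter(.data$pre_type %in% source_mbon) |>
    dplyr::summarise(x = sum(.data$synapse_count), .by = "post_type") |>
    dplyr::rename(cell_type = "post_type")
  y_tab <- te |>
    dplyr::filter(.data$post_type %in% target_dans) |>
    dplyr::summarise(y = sum(.data$synapse_count), .by = "pre_type") |>
    dplyr::rename(cell_type = "pre_type")
  out <- candidates |>
    dplyr::select("cell_type") |>
    dplyr::left_join(x_tab, by = "cell_type") |>
    dplyr::left_join(y_tab, by = "cell_type") |>
    dplyr::mutate(dplyr::across(c("x", "y"), ~ tidyr::replace_na(.x, 0L)),
                  product = as.numeric(.data$x) * as.numeric(.data$y))
  cut <- quantile(out$product, outlier_quantile, names = FALSE)
  out |>
    dplyr::mutate(outlier = .data$product >= cut & .data$product > 0) |>
    dplyr::arrange(dplyr::desc(.data$product))
}

#' Rank cholinergic cell types by their synaptic output onto DANs
#'
#' Restricts to cell types whose predicted transmitter is acetylcholine and
#' ranks them by total synapses onto the given DAN set, descending; ties are
#' broken by cell-type name. An empty result (no cholinergic neurons) is
#' returned as an empty tibble, not an error.
#'
#' @param cn A [connectome()].
#' @param dan_set Non-empty character vector of DAN cell types.
#' @return A tibble `rank`, `cell_type`, `synapses_to_dans`.
#' @export
rank_cholinergic_by_dan_output <- function(cn, dan_set = NULL) {
  stopifnot(inherits(cn, "connectome"))
  tc <- type_class(cn)
  if (is.null(dan_set)) dan_set <- tc$cell_type[tc$class == "DAN"]
  if (length(dan_set) == 0) {
    abort("dan_set must be non-empty", class = "mblearn_argument_error")
  }
  chol <- type_nt(cn) |>
    dplyr::filter(.data$predicted_nt == "acetylcholine")
  out <- type_edges(cn) |>
    dplyr::filter(.data$pre_type %in% chol$cell_type,
                  .data$post_type %in% dan_set) |>
    dplyr::summarise(synapses_to_dans = sum(.data$synapse_count),
                     .by = "pre_type") |>
    dplyr::rename(cell_type = "pre_type") |>
    dplyr::arrange(dplyr::desc(.data$synapses_to_dans), .data$cell_type)
  out |> dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
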