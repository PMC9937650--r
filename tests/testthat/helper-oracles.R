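# Independent oracles and small fixture builders shared across the suite.

# Toy connectome from compact edge specs: list of c(pre, post, count).
toy_connectome <- function(neurons, edges) {
  edf <- purrr::map_dfr(edges, function(e) {
    tibble::tibble(pre_id = e[[1]], post_id = e[[2]],
                   synapse_count = as.integer(e[[3]]))
  })
  connectome(neurons, edf)
}

# Neuron table where id == cell_type (one neuron per type keeps the
# type-level and neuron-level views identical in toy graphs).
toy_neurons <- function(ids, classes, nts = NULL) {
  tibble::tibble(neuron_id = ids, cell_type = ids, class = classes,
                 predicted_nt = nts %||% rep("unknown", length(ids)))
}

# Brute-force pathway enumeration: tries every ordered tuple of distinct
# intermediate types, checking each hop against the aggregated edge table.
bf_enumerate <- function(cn, source, targets, max_interneurons,
                         min_edge_count) {
  te <- mblearn:::type_edges(cn)
  cnt <- function(a, b) {
    hit <- te$synapse_count[te$pre_type == a & te$post_type == b]
    if (length(hit) == 0) 0L else hit[1]
  }
  tc <- mblearn:::type_class(cn)
  inter <- tc$cell_type[!tc$class %in% c("MBON", "DAN", "KC")]
  inter <- setdiff(inter, source)
  keys <- character()
  ok <- function(...) all(vapply(list(...), function(h) h >= min_edge_count,
                                 logical(1)))
  for (tg in intersect(targets, tc$cell_type)) {
    if (tg == source) next
    if (ok(cnt(source, tg))) {
      keys <- c(keys, paste(source, "", "", tg, sep = "|"))
    }
    if (max_interneurons >= 1) {
      for (i1 in setdiff(inter, tg)) {
        if (ok(cnt(source, i1), cnt(i1, tg))) {
          keys <- c(keys, paste(source, i1, "", tg, sep = "|"))
        }
        if (max_interneurons >= 2) {
          for (i2 in setdiff(inter, c(i1, tg))) {
            if (ok(cnt(source, i1), cnt(i1, i2), cnt(i2, tg))) {
              keys <- c(keys, paste(source, i1, i2, tg, sep = "|"))
            }
          }
        }
      }
    }
  }
  sort(keys)
}

pathway_keys <- function(paths) {
  if (nrow(paths) == 0) return(character())
  sort(paste(paths$source,
             tidyr::replace_na(paths$via1, ""),
             tidyr::replace_na(paths$via2, ""),
             paths$target, sep = "|"))
}

# Random directed graph over <= 30 nodes with MBON/DAN/interneuron classes.
random_connectome <- function(seed, n_nodes = NULL) {
  withr::with_seed(seed, {
    n <- n_nodes %||% sample(8:30, 1)
    classes <- sample(c("MBON", "DAN", "interneuron"), n, replace = TRUE,
                      prob = c(0.2, 0.3, 0.5))
    # guarantee at least one source and one target
    classes[1] <- "MBON"
    classes[2] <- "DAN"
    ids <- sprintf("n%02d", seq_len(n))
    neurons <- toy_neurons(ids, classes,
                           sample(c("acetylcholine", "GABA", "unknown"),
                                  n, replace = TRUE))
    pairs <- expand.grid(pre_id = ids, post_id = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$pre_id != pairs$post_id, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.2, ]
    edges <- tibble::tibble(pre_id = pairs$pre_id, post_id = pairs$post_id,
                            synapse_count = sample(1:40, nrow(pairs),
                                                   replace = TRUE))
    connectome(neurons, edges)
  })
}

# Box-constrained quadratic minimisation as an NNLS oracle, multistart.
bf_nnls <- function(A, b) {
  obj <- function(w) sum((b - A %*% w)^2)
  gr <- function(w) as.vector(-2 * t(A) %*% (b - A %*% w))
  k <- ncol(A)
  starts <- list(rep(0, k), rep(0.5, k), rep(1, k))
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, gr, method = "L-BFGS-B", lower = rep(0, k),
                 control = list(maxit = 500, factr = 1e4))
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]$par
}

# Per-frame fly-by-fly PI count, the counting oracle.
bf_frame_pi <- function(x, y, odor_quadrants, geometry) {
  q <- vapply(seq_along(x), function(i) {
    th <- atan2(y[i], x[i]) * 180 / pi
    rel <- (th - geometry$offset_deg) %% 360
    as.integer(rel %/% 90) + 1L
  }, integer(1))
  n_odor <- sum(q %in% odor_quadrants)
  (n_odor - (length(q) - n_odor)) / length(q)
}

# One-call composite curve whose log-odds are an exact weighted sum of
# basis log-odds (no noise, no clipping).
mix_curves <- function(basis, weights) {
  wtab <- tibble::tibble(driver = unique(basis$driver), w = weights)
  basis |>
    dplyr::inner_join(wtab, by = "driver") |>
    dplyr::summarise(
      r = sum(.w_r(.data$pi) * .data$w), .by = c("phase", "trial")) |>
    dplyr::transmute(phase = .data$phase, trial = .data$trial,
                     pi = 2 * stats::plogis(.data$r) - 1)
}
.w_r <- function(p) log_odds(pi_to_prob(p))
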