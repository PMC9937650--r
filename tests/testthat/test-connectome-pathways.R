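test_that("connectome loading parses, merges duplicate edges, and rejects bad schemas", {
  ndir <- withr::local_tempdir()
  npath <- file.path(ndir, "neurons.csv")
  epath <- file.path(ndir, "edges.csv")
  writeLines(c("neuron_id,cell_type,class,predicted_nt",
               "a,MBON01,MBON,glutamate",
               "b,INT01,interneuron,acetylcholine",
               "c,PAM01,DAN,dopamine"), npath)
  writeLines(c("pre_id,post_id,synapse_count",
               "a,b,5", "b,c,7"), epath)
  cn <- suppressMessages(load_connectome(npath, epath))
  expect_equal(nrow(cn$neurons), 3)
  expect_equal(nrow(cn$edges), 2)

  # duplicate (pre, post) rows sum into one edge
  writeLines(c("pre_id,post_id,synapse_count",
               "a,b,5", "a,b,7"), epath)
  cn2 <- suppressMessages(load_connectome(npath, epath))
  expect_equal(nrow(cn2$edges), 1)
  expect_equal(cn2$edges$synapse_count, 12L)

  # edge referencing a missing neuron names the offending row
  writeLines(c("pre_id,post_id,synapse_count", "a,x,3"), epath)
  expect_error(suppressMessages(load_connectome(npath, epath)),
               "row 1.*x", class = "mblearn_schema_error")

  # non-positive or fractional synapse counts are schema errors
  writeLines(c("pre_id,post_id,synapse_count", "a,b,0"), epath)
  expect_error(suppressMessages(load_connectome(npath, epath)),
               class = "mblearn_schema_error")
  writeLines(c("pre_id,post_id,synapse_count", "a,b,2.5"), epath)
  expect_error(suppressMessages(load_connectome(npath, epath)),
               class = "mblearn_schema_error")

  # unknown classes fall back to "other", missing nt to "unknown"
  cn3 <- connectome(
    toy_neurons(c("a", "b"), c("MBON", "mystery")),
    tibble::tibble(pre_id = "a", post_id = "b", synapse_count = 1L))
  expect_equal(cn3$neurons$class[2], "other")
  expect_true(all(cn3$neurons$predicted_nt == "unknown"))
})

test_that("the >=100 total-synapse screen is inclusive and excludes MBON/DAN/KC classes", {
  neurons <- toy_neurons(
    c("MBON-a1", "PAM01", "I100", "I99", "KC1"),
    c("MBON", "DAN", "interneuron", "interneuron", "KC"))
  cn <- toy_connectome(neurons, list(
    c("MBON-a1", "I100", 60), c("I100", "PAM01", 40),   # total exactly 100
    c("MBON-a1", "I99", 60), c("I99", "PAM01", 39),     # total 99
    c("MBON-a1", "KC1", 500), c("KC1", "PAM01", 500),   # KC: never a candidate
    c("MBON-a1", "PAM01", 500)))                        # MBON: never a candidate
  got <- core_interneurons(cn, "MBON-a1", "PAM01")
  expect_equal(got$cell_type, "I100")
  expect_equal(got$synapses_in, 60L)
  expect_equal(got$synapses_out, 40L)
  expect_equal(got$total, 100L)

  expect_error(core_interneurons(cn, character(), "PAM01"),
               class = "mblearn_argument_error")
  expect_error(core_interneurons(cn, "MBON-a1", "MBON-a1"),
               class = "mblearn_argument_error")
})

test_that("pathway enumeration honours hop bounds, thresholds and simple-path rules", {
  neurons <- toy_neurons(
    c("MBON-a1", "I1", "I2", "PAM01"),
    c("MBON", "interneuron", "interneuron", "DAN"),
    c("glutamate", "acetylcholine", "GABA", "dopamine"))
  cn <- toy_connectome(neurons, list(
    c("MBON-a1", "I1", 30), c("I1", "PAM01", 20),
    c("I1", "I2", 15), c("I2", "I1", 9), c("I2", "PAM01", 5)))

  one <- enumerate_pathways(cn, "MBON-a1", "PAM01", max_interneurons = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$counts[[1]], c(30L, 20L))
  expect_equal(one$nts[[1]], c("glutamate", "acetylcholine"))
  expect_equal(one$strength, 20)

  # the two-interneuron chain appears only when max_interneurons = 2
  two <- enumerate_pathways(cn, "MBON-a1", "PAM01", max_interneurons = 2)
  expect_equal(nrow(two), 2)
  expect_true(any(!is.na(two$via2) & two$via2 == "I2"))
  # cycle I1 <-> I2 terminates; no node repeats in any path
  expect_true(all(purrr::map_lgl(seq_len(nrow(two)), function(i) {
    nodes <- stats::na.omit(c(two$source[i], two$via1[i], two$via2[i],
                              two$target[i]))
    !anyDuplicated(nodes)
  })))

  # per-hop threshold prunes the weak I2 -> PAM01 hop
  strong <- enumerate_pathways(cn, "MBON-a1", "PAM01", max_interneurons = 2,
                               min_edge_count = 10)
  expect_equal(nrow(strong), 1)

  expect_error(enumerate_pathways(cn, "nope", "PAM01"),
               class = "mblearn_argument_error")
  expect_error(enumerate_pathways(cn, "MBON-a1", character()),
               class = "mblearn_argument_error")
})

test_that("pathway strength rules evaluate and aggregate as defined", {
  expect_equal(pathway_strength(c(30, 20)), 20)
  expect_equal(pathway_strength(c(30, 20), "geometric_mean"), sqrt(600))
  # parallel one-hop paths aggregate by summing per-path strengths
  neurons <- toy_neurons(c("M", "Ia", "Ib", "D"),
                         c("MBON", "interneuron", "interneuron", "DAN"))
  cn <- toy_connectome(neurons, list(
    c("M", "Ia", 10), c("Ia", "D", 10),
    c("M", "Ib", 5), c("Ib", "D", 5)))
  paths <- enumerate_pathways(cn, "M", "D", max_interneurons = 1)
  agg <- paths |>
    dplyr::summarise(s = sum(strength), .by = c("source", "target"))
  expect_equal(agg$s, 15)
})

test_that("enumeration agrees exactly with brute-force search on random graphs", {
  for (s in 1:30) {
    cn <- random_connectome(seed = 1000 + s)
    tc <- mblearn:::type_class(cn)
    src <- tc$cell_type[tc$class == "MBON"][1]
    tgt <- tc$cell_type[tc$class == "DAN"]
    k <- withr::with_seed(s, sample(0:2, 1))
    m <- withr::with_seed(s + 99, sample(c(1, 10, 25), 1))
    got <- pathway_keys(enumerate_pathways(cn, src, tgt, k, m))
    want <- bf_enumerate(cn, src, tgt, k, m)
    expect_identical(got, want)
  }
})

test_that("tightening thresholds or hop bounds never adds pathways", {
  for (s in 1:8) {
    cn <- random_connectome(seed = 2000 + s)
    tc <- mblearn:::type_class(cn)
    src <- tc$cell_type[tc$class == "MBON"][1]
    tgt <- tc$cell_type[tc$class == "DAN"]
    base <- pathway_keys(enumerate_pathways(cn, src, tgt, 2, 1))
    expect_true(all(pathway_keys(enumerate_pathways(cn, src, tgt, 2, 10)) %in% base))
    expect_true(all(pathway_keys(enumerate_pathways(cn, src, tgt, 1, 1)) %in% base))
    expect_true(all(pathway_keys(enumerate_pathways(cn, src, tgt, 0, 1)) %in% base))
  }
})

test_that("pathway intermediates pass the candidate screen run at the same threshold", {
  for (s in 1:5) {
    cn <- random_connectome(seed = 3000 + s)
    tc <- mblearn:::type_class(cn)
    src <- tc$cell_type[tc$class == "MBON"][1]
    tgt <- tc$cell_type[tc$class == "DAN"]
    paths <- enumerate_pathways(cn, src, tgt, 2, min_edge_count = 30)
    if (nrow(paths) == 0) next
    cand <- core_interneurons(cn,
                              mbon_set = tc$cell_type[tc$class == "MBON"],
                              dan_set = tc$cell_type[tc$class == "DAN"],
                              min_total = 30)
    mids <- stats::na.omit(c(paths$via1, paths$via2))
    expect_true(all(mids %in% cand$cell_type))
  }
})

test_that("input/output scatter flags the planted hub and respects the target set", {
  cn <- gen_connectome(synth_config(seed = 21))
  tc <- mblearn:::type_class(cn)
  dans <- tc$cell_type[tc$class == "DAN"]
  cand <- core_interneurons(cn)
  sc <- input_output_scatter(cn, "MBON01", dans, cand)
  expect_true(sc$outlier[sc$cell_type == cn$metadata$hub_cell_type])

  # candidate with no edge onto any target DAN scores y = 0
  neurons <- toy_neurons(c("M", "I", "D1", "D2"),
                         c("MBON", "interneuron", "DAN", "DAN"))
  cn2 <- toy_connectome(neurons, list(c("M", "I", 120), c("I", "D2", 50)))
  cand2 <- core_interneurons(cn2, "M", c("D1", "D2"))
  sc2 <- input_output_scatter(cn2, "M", "D1", cand2)
  expect_equal(sc2$y, 0L)
  # the same candidate counted against the full target set picks up D2
  sc3 <- input_output_scatter(cn2, "M", c("D1", "D2"), cand2)
  expect_equal(sc3$y, 50L)
  expect_error(input_output_scatter(cn2, "M", "D1", cand2[0, ]),
               class = "mblearn_argument_error")
})

test_that("cholinergic ranking filters by transmitter and tolerates an empty field", {
  neurons <- toy_neurons(
    c("A", "B", "G", "D"),
    c("interneuron", "interneuron", "interneuron", "DAN"),
    c("acetylcholine", "acetylcholine", "GABA", "dopamine"))
  cn <- toy_connectome(neurons, list(
    c("A", "D", 50), c("B", "D", 80), c("G", "D", 500)))
  rk <- rank_cholinergic_by_dan_output(cn, "D")
  expect_equal(rk$cell_type, c("B", "A"))
  expect_equal(rk$rank, c(1L, 2L))
  expect_false("G" %in% rk$cell_type)

  # synthetic hub is cholinergic with the most DAN synapses: rank 1
  cng <- gen_connectome(synth_config(seed = 13))
  rkg <- rank_cholinergic_by_dan_output(cng)
  expect_equal(rkg$cell_type[1], cng$metadata$hub_cell_type)

  # no cholinergic neurons: empty table, not an error
  cn0 <- toy_connectome(toy_neurons(c("G", "D"), c("interneuron", "DAN"),
                                    c("GABA", "dopamine")),
                        list(c("G", "D", 10)))
  expect_equal(nrow(rank_cholinergic_by_dan_output(cn0, "D")), 0)
})
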