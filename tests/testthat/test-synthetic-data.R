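test_that("event application matches worked examples", {
  anc <- ancestral_order()
  # length-1 inversion at trnQ flips only its sign
  flip <- apply_event(anc, list(kind = "inversion", start = 8, len = 1))
  expect_equal(flip$genes$symbol, anc$genes$symbol)
  expect_equal(flip$genes$sign[8L], 1L)  # ancestral trnQ is -1
  expect_equal(flip$genes$sign[-8L], anc$genes$sign[-8L])

  # trnS1 transposed past trnH reproduces the crocodilian order
  croc <- apply_event(anc, list(kind = "transposition", start = 30, len = 1, dest = 28))
  expect_equal(croc$genes$symbol[28:31], c("nad4", "trnS1", "trnH", "trnL2"))

  # TDRL over (cob, trnT, trnP): duplicate in tandem, drop one copy of each
  td <- apply_event(anc, list(kind = "tdrl", start = 35, len = 3,
                              keep_first = c(FALSE, TRUE, FALSE)))
  expect_equal(sort(td$genes$symbol), sort(anc$genes$symbol))  # content kept
  expect_equal(td$genes$symbol[td$genes$symbol %in% c("cob", "trnT", "trnP")],
               c("trnT", "cob", "trnP"))
  # retained duplicates keep both copies
  td2 <- apply_event(anc, list(kind = "tdrl", start = 35, len = 3,
                               keep_first = c(FALSE, TRUE, FALSE),
                               retain_both = 2L))
  expect_equal(sum(td2$genes$symbol == "trnT"), 2L)

  # duplication inserts a tandem copy; deletion removes one occurrence
  dup <- apply_event(anc, list(kind = "duplication", start = 9))
  expect_equal(dup$genes$symbol[9:10], c("trnM", "trnM"))
  expect_equal(dup$genes$copy_index[9:10], c(1L, 2L))
  del <- apply_event(anc, list(kind = "deletion", start = 37))
  expect_equal(nrow(del$genes), 36L)
  expect_false("trnP" %in% del$genes$symbol)
  expect_error(apply_event(anc, list(kind = "inversion", start = 1, len = 40)),
               "block")
})

test_that("events conserve gene content as specified", {
  set.seed(3)
  cfg <- simulation_config(seed = 3)
  anc <- ancestral_order()
  for (i in 1:50) {
    spec <- mitorearr:::.random_event_spec(37L, cfg)
    out <- apply_event(anc, spec)
    if (spec$kind %in% c("transposition", "reverse_transposition",
                         "inversion", "tdrl")) {
      expect_equal(sort(out$genes$symbol), sort(anc$genes$symbol),
                   label = spec$kind)
    } else if (spec$kind == "duplication") {
      expect_equal(nrow(out$genes), 38L)
    } else {
      expect_equal(nrow(out$genes), 36L)
    }
  }
})

test_that("genome simulation is deterministic and replay reproduces genomes", {
  cfg <- simulation_config(seed = 99)
  g1 <- simulate_genome(cfg, "g", genome_index = 4L)
  g2 <- simulate_genome(cfg, "g", genome_index = 4L)
  expect_identical(g1$arch$genes, g2$arch$genes)
  expect_identical(g1$truth$events, g2$truth$events)
  # replay oracle: folding the truth log from the ancestral order
  found <- 0L
  for (i in 1:40) {
    sim <- simulate_genome(cfg, paste0("g", i), genome_index = i)
    if (!isTRUE(sim$truth$rearranged)) next
    found <- found + 1L
    expect_equal(architecture_key(replay_events(sim$truth$events)),
                 architecture_key(sim$arch))
  }
  expect_gt(found, 5L)
})

test_that("zero error rate injects nothing; injected errors are logged", {
  cfg <- simulation_config(seed = 12, error_rate = 0)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d$evidence), 0L)
  expect_true(all(vapply(d$truth, function(t) nrow(t$errors) == 0L, logical(1))))

  cfg2 <- simulation_config(seed = 12, error_rate = 0.05)
  d2 <- simulate_dataset(cfg2)
  n_err <- sum(vapply(d2$truth, function(t) nrow(t$errors), integer(1)))
  expect_gt(n_err, 0L)
  expect_equal(nrow(d2$evidence), n_err)
  # evidence rows correspond one-to-one to logged errors
  logged <- do.call(rbind, lapply(d2$truth, function(t) {
    if (nrow(t$errors)) data.frame(genome_id = t$genome_id, t$errors)
  }))
  expect_setequal(paste(d2$evidence$genome_id, d2$evidence$symbol),
                  paste(logged$genome_id, logged$symbol))
})

test_that("dataset simulation is byte-identical across runs and readable back", {
  cfg <- simulation_config(seed = 42, n_classes = 2, orders_per_class = 2,
                           species_per_order = 3, plant_convergence = TRUE,
                           synonym_labels = TRUE)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in c("annotations.tsv", "taxonomy.tsv", "evidence.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # fixture is self-contained: the IO layer reads it back into architectures
  ann <- read_architecture_tsv(file.path(d1, "annotations.tsv"))
  tax <- read_taxonomy_tsv(file.path(d1, "taxonomy.tsv"))
  archs <- build_architectures(ann)
  expect_equal(length(archs), nrow(tax))
  # synonym labels (tRNA-Phe, ND1, ...) normalize back to canonical symbols
  expect_true(all(vapply(archs, function(a)
    all(a$genes$symbol %in% gene_vocabulary()$symbol), logical(1))))
})

test_that("rearranged genomes always differ from the ancestral architecture", {
  cfg <- simulation_config(seed = 8, n_classes = 2, orders_per_class = 2,
                           species_per_order = 10)
  d <- simulate_dataset(cfg)
  for (id in names(d$architectures)) {
    a <- d$architectures[[id]]
    np <- a
    np$genes <- np$genes[!np$genes$pseudo, , drop = FALSE]
    if (isTRUE(d$truth[[id]]$rearranged)) {
      expect_false(architecture_key(np) == ancestral_key(), label = id)
    } else {
      expect_equal(architecture_key(np), ancestral_key())
    }
  }
})
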