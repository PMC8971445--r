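test_that("ancestral genomes have an empty moved set, invariant under rotation", {
  anc <- ancestral_order()
  expect_equal(nrow(moved_gene_set(anc)$moved), 0L)
  rot <- anc
  rot$genes <- rbind(anc$genes[-(1:12), ], anc$genes[1:12, ])
  expect_equal(nrow(moved_gene_set(rot)$moved), 0L)
  expect_equal(nrow(moved_gene_set(rot)$in_place), 37L)
})

test_that("the crocodilian trnS1/trnH exchange is a single trnS1 transposition", {
  croc <- apply_event(ancestral_order("croc"),
                      list(kind = "transposition", start = 30, len = 1, dest = 28))
  rep <- moved_gene_set(croc)
  expect_equal(rep$moved$symbol, "trnS1")
  ev <- classify_events(croc, rep)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "translocation")
  expect_equal(ev$reported_class, "inv_tra")
})

test_that("an inverted block marks exactly its members as moved", {
  # toy 5-gene circular order with one inverted block of length 2
  v <- c(1L, -3L, -2L, 4L, 5L)
  rep <- moved_gene_set(toy_arch(v))
  expect_setequal(rep$moved$symbol, .voc$symbol[2:3])
  expect_equal(sort(brute_moved(v)), 2:3)
})

test_that("moved sets equal the brute-force minimal-removal search (n = 4, 5)", {
  for (n in 4:5) {
    for (v in signed_circular_reps(n)) {
      got <- sort(match(moved_gene_set(toy_arch(v))$moved$symbol, .voc$symbol))
      expect_identical(as.integer(got), as.integer(brute_moved(v)),
                       label = paste("perm", paste(v, collapse = ",")))
    }
  }
})

test_that("event classification covers duplications, deletions, inversions", {
  # extra trnM copy, otherwise ancestral
  dup <- apply_event(ancestral_order("d"), list(kind = "duplication", start = 9))
  ev <- classify_events(dup)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev[, c("symbol", "copy_index", "kind")],
               data.frame(symbol = "trnM", copy_index = 2L,
                          kind = "duplication"))

  # missing trnP
  del <- apply_event(ancestral_order("e"), list(kind = "deletion", start = 37))
  ev <- classify_events(del)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$symbol, "trnP")

  # trnQ annotated on the heavy strand in its ancestral position
  flip <- ancestral_order("f")
  flip$genes$sign[8L] <- 1L
  ev <- classify_events(flip)
  expect_equal(ev$kind, "inversion")
  expect_equal(ev$symbol, "trnQ")

  # pseudogene copies are never events and never gene presence
  ps <- apply_event(ancestral_order("p"),
                    list(kind = "duplication", start = 35, pseudo = TRUE))
  expect_equal(nrow(classify_events(ps)), 0L)
  rep <- moved_gene_set(ps)
  expect_equal(nrow(rep$moved) + nrow(rep$in_place), 37L)
})

test_that("instance conservation: each occurrence in at most one inv/tra event", {
  set.seed(11)
  cfg <- simulation_config(seed = 11)
  for (i in 1:30) {
    sim <- simulate_genome(cfg, paste0("g", i), genome_index = i)
    ev <- classify_events(sim$arch)
    it <- ev[ev$reported_class == "inv_tra", ]
    expect_equal(anyDuplicated(paste(it$symbol, it$copy_index)), 0L)
    # moved/in_place partition all non-pseudo occurrences
    rep <- moved_gene_set(sim$arch)
    np <- sum(!sim$arch$genes$pseudo)
    expect_equal(nrow(rep$moved) + nrow(rep$in_place), np)
    # minimality: removing every touched occurrence restores the ancestral
    # order, so the moved set can never be larger than that
    if (isTRUE(sim$truth$rearranged)) {
      touched_now <- sum(!sim$arch$genes$pseudo &
                           match(sim$arch$genes$symbol, .voc$symbol) %in%
                             sim$truth$touched)
      expect_lte(nrow(rep$moved), touched_now)
    }
  }
})

test_that("evidence screening refutes only demonstrable annotation errors", {
  # inversion of trnE whose sequence sits on the ancestral (light) strand
  flip <- ancestral_order("g1")
  flip$genes$sign[34L] <- 1L
  ev <- classify_events(flip)
  evidence <- data.frame(genome_id = "g1", symbol = "trnE", copy_index = 1L,
                         verified_strand = "-", identity_fraction = 0.95,
                         located = TRUE, stringsAsFactors = FALSE)
  out <- screen_annotation_errors(ev, evidence)
  expect_equal(out$status, "refuted")
  expect_equal(out$reason, "wrong_strand_annotation")

  # below the 80% identity threshold the inversion stands
  evidence$identity_fraction <- 0.70
  out <- screen_annotation_errors(ev, evidence)
  expect_equal(out$status, "confirmed")

  # unannotated nad6 located in the genome refutes the deletion
  del <- ancestral_order("g2")
  del$genes <- del$genes[del$genes$symbol != "nad6", ]
  ev <- classify_events(del)
  evidence <- data.frame(genome_id = "g2", symbol = "nad6", copy_index = 1L,
                         verified_strand = "unknown",
                         identity_fraction = NA_real_, located = TRUE,
                         stringsAsFactors = FALSE)
  out <- screen_annotation_errors(ev, evidence)
  expect_equal(out$status, "refuted")
  expect_equal(out$reason, "unannotated_not_deleted")

  # no evidence at all: everything is confirmed by default
  croc <- apply_event(ancestral_order("g3"),
                      list(kind = "transposition", start = 30, len = 1, dest = 28))
  out <- screen_annotation_errors(classify_events(croc), NULL)
  expect_equal(out$status, "confirmed")
  expect_error(screen_annotation_errors(out, NULL, identity_threshold = 0),
               "identity_threshold")
  expect_error(screen_annotation_errors(out, NULL, identity_threshold = 1.2),
               "identity_threshold")
})

test_that("genome_is_rearranged reflects confirmed events only", {
  ev <- data.frame(genome_id = "g", symbol = "trnP", copy_index = 1L,
                   kind = "deletion", reported_class = "del",
                   status = "refuted", reason = "unannotated_not_deleted",
                   stringsAsFactors = FALSE)
  expect_false(genome_is_rearranged(ev))
  ev$status <- "confirmed"
  expect_true(genome_is_rearranged(ev))
  expect_false(genome_is_rearranged(ev[0, ]))
})
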