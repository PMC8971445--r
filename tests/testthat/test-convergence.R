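test_that("architecture keys are rotation-invariant and content-sensitive", {
  anc <- ancestral_order()
  rot <- anc
  rot$genes <- rbind(anc$genes[-(1:7), ], anc$genes[1:7, ])
  expect_equal(architecture_key(rot), ancestral_key())
  croc <- apply_event(ancestral_order(),
                      list(kind = "transposition", start = 30, len = 1, dest = 28))
  expect_false(architecture_key(croc) == ancestral_key())
  # identical duplication patterns serialize identically
  d1 <- apply_event(ancestral_order("a"), list(kind = "duplication", start = 9))
  d2 <- apply_event(ancestral_order("b"), list(kind = "duplication", start = 9))
  expect_equal(architecture_key(d1), architecture_key(d2))
  expect_false(architecture_key(d1) == ancestral_key())
})

test_that("signatures name moved runs, duplications and deletions", {
  expect_equal(rearrangement_signature(ancestral_order()), character(0))
  delP <- ancestral_order("x")
  delP$genes <- delP$genes[delP$genes$symbol != "trnP", ]
  expect_equal(rearrangement_signature(delP), "deletion:trnP")
  dupP <- apply_event(ancestral_order("y"), list(kind = "duplication", start = 37))
  expect_equal(rearrangement_signature(dupP), "duplication:trnP")
  croc <- apply_event(ancestral_order("z"),
                      list(kind = "transposition", start = 30, len = 1, dest = 28))
  expect_equal(rearrangement_signature(croc), "inv_tra:trnS1")
  # a two-gene inverted block yields one signed run element
  inv <- apply_event(ancestral_order("w"), list(kind = "inversion", start = 35, len = 2))
  expect_equal(rearrangement_signature(inv), "inv_tra:-trnT,-cob")
})

test_that("convergence grouping respects the taxonomic rank gate", {
  croc_spec <- list(kind = "transposition", start = 30, len = 1, dest = 28)
  archs <- list(
    a1 = canonicalize(apply_event(ancestral_order("a1"), croc_spec)),
    b1 = canonicalize(apply_event(ancestral_order("b1"), croc_spec)),
    c1 = ancestral_order("c1")
  )
  taxonomy <- data.frame(genome_id = c("a1", "b1", "c1"),
                         species = c("sa", "sb", "sc"),
                         class = c("C1", "C2", "C1"),
                         order = c("O1", "O2", "O3"),
                         stringsAsFactors = FALSE)
  for (mode in c("whole_architecture", "signature")) {
    conv <- find_convergences(archs, taxonomy, rank = "order", mode = mode)
    expect_equal(nrow(conv), 1L)
    expect_equal(conv$n_genomes, 2L)
    expect_equal(conv$genomes, "a1,b1")
  }
  # same order: the shared arrangement is not counted as convergent
  taxonomy$order <- c("O1", "O1", "O2")
  conv <- find_convergences(archs, taxonomy, rank = "order")
  expect_equal(nrow(conv), 0L)
  # but at class rank the two classes still qualify
  conv <- find_convergences(archs, taxonomy, rank = "class")
  expect_equal(nrow(conv), 1L)
  # all-ancestral input: nothing to group
  anc3 <- list(a1 = ancestral_order("a1"), b1 = ancestral_order("b1"),
               c1 = ancestral_order("c1"))
  expect_equal(nrow(find_convergences(anc3, taxonomy)), 0L)
})

test_that("breakpoint distance is a proper dissimilarity on anchored circles", {
  anc <- to_signed_permutation(ancestral_order())
  expect_equal(breakpoint_distance(anc, anc), 0L)
  croc <- to_signed_permutation(canonicalize(apply_event(
    ancestral_order(), list(kind = "transposition", start = 30, len = 1, dest = 28))))
  # adjacent exchange breaks exactly 3 of the 37 circular adjacencies
  expect_equal(breakpoint_distance(anc, croc), 3L)
  expect_equal(breakpoint_distance(croc, anc), 3L)
  set.seed(5)
  for (i in 1:20) {
    v1 <- sperm(sample(8) * sample(c(-1, 1), 8, replace = TRUE))
    v2 <- sperm(sample(8) * sample(c(-1, 1), 8, replace = TRUE))
    expect_equal(breakpoint_distance(v1, v2), breakpoint_distance(v2, v1))
    expect_equal(breakpoint_distance(v1, v1), 0L)
  }
  expect_error(breakpoint_distance(sperm(1:4), sperm(1:5)), "content")
})

test_that("inversion bound matches worked single- and double-block cases", {
  anc <- to_signed_permutation(ancestral_order())
  expect_equal(inversion_distance_bound(anc, anc), 0L)
  one <- to_signed_permutation(canonicalize(apply_event(
    ancestral_order(), list(kind = "inversion", start = 10, len = 4))))
  expect_equal(inversion_distance_bound(anc, one), 1L)
  two <- to_signed_permutation(canonicalize(apply_event(
    canonicalize(apply_event(ancestral_order(),
                             list(kind = "inversion", start = 10, len = 4))),
    list(kind = "inversion", start = 20, len = 3))))
  expect_equal(inversion_distance_bound(anc, two), 2L)
})

test_that("inversion bound equals BFS-exact distance on all small instances", {
  # exhaustive at n = 4: every signed linear permutation
  ball <- reversal_ball(4, 7)
  perms4 <- signed_circular_reps(4)
  # extend representatives to all permutations by resampling first element
  set.seed(7)
  for (v in perms4) {
    b <- inversion_distance_bound(sperm(v), sperm(1:4))
    e <- ball_distance(ball, v)
    expect_false(is.na(e))
    expect_equal(b, e, label = paste(v, collapse = ","))
  }
})

test_that("distance matrix partitions by zero distance", {
  croc <- canonicalize(apply_event(
    ancestral_order(), list(kind = "transposition", start = 30, len = 1, dest = 28)))
  perms <- list(a = to_signed_permutation(ancestral_order("a")),
                b = to_signed_permutation(ancestral_order("b")),
                c = to_signed_permutation(ancestral_order("c")),
                d = to_signed_permutation(croc))
  dm <- distance_matrix(perms, inversion = TRUE)
  expect_true(all(diag(dm$breakpoint) == 0L))
  expect_true(all(diag(dm$inversion) == 0L))
  expect_equal(unname(dm$zero_partition), c(1L, 1L, 1L, 2L))
  expect_equal(unname(table(dm$zero_partition)), array(c(3L, 1L)),
               ignore_attr = TRUE)
  expect_true(isSymmetric(dm$breakpoint))
})
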