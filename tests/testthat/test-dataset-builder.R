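make_proteins <- function() {
  protein_set(
    id = c("ok1", "short", "multi", "ambig", "noloc", "ok2"),
    seq = c(strrep("ACDEFGHIKL", 6), strrep("A", 49),
            strrep("ACDEFGHIKL", 5), strrep("ACDEFGHIKL", 5),
            strrep("ACDEFGHIKL", 5), strrep("MKWVTFISLL", 7)),
    compartment = c("nucleus", "nucleus", "nucleus;cytoplasm",
                    "cytoplasm (probable)", NA, "cytoplasm"),
    strict = FALSE
  )
}

test_that("benchmark filters remove short, ambiguous and multi-location entries", {
  res <- filter_proteins(make_proteins())
  expect_identical(res$kept$id, c("ok1", "ok2"))
  rules <- setNames(res$rejected$rule, res$rejected$id)
  expect_identical(rules[["short"]], "min_length")
  expect_identical(rules[["multi"]], "multiple_locations")
  expect_identical(rules[["ambig"]], "ambiguous_location")
  expect_identical(rules[["noloc"]], "missing_location")
})

test_that("filters log non-standard residues and pass clean input unchanged", {
  p <- protein_set(c("a", "b"), c(strrep("ACDEFGHIKL", 6), strrep("ACDEFGHIXL", 6)),
                   c("nucleus", "nucleus"), strict = FALSE)
  res <- filter_proteins(p)
  expect_identical(res$kept$id, "a")
  expect_identical(res$rejected$rule, "nonstandard_residue")
  clean <- protein_set(c("a", "b"), rep(strrep("ACDEFGHIKL", 6), 2),
                       c("nucleus", "cytoplasm"))
  res2 <- filter_proteins(clean)
  expect_identical(nrow(res2$kept), 2L)
  expect_identical(nrow(res2$rejected), 0L)
  only_short <- protein_set("x", strrep("A", 10), "nucleus")
  expect_error(filter_proteins(only_short), "filtered out")
})

test_that("negative sampling enumerates the exhaustive cross-compartment case", {
  p <- protein_set(paste0("p", 1:5), replicate(5, strrep("ACDEFGHIKL", 6)),
                   c("a", "a", "a", "b", "b"))
  neg <- sample_negatives(p, 6, seed = 1)
  expect_identical(nrow(neg), 6L)
  key <- paste(pmin(neg$idA, neg$idB), pmax(neg$idA, neg$idB))
  expect_identical(length(unique(key)), 6L)  # exactly the 6 cross pairs
  comp <- setNames(p$compartment, p$id)
  expect_true(all(comp[neg$idA] != comp[neg$idB]))
  expect_identical(nrow(sample_negatives(p, 0, seed = 1)), 0L)
  expect_error(sample_negatives(p, 7, seed = 1), "only 6")
})

test_that("negative sampling is seed-reproducible and respects exclusions", {
  set.seed(20)
  p <- protein_set(sprintf("q%03d", 1:100),
                   replicate(100, random_protein(60)),
                   paste0("c", rep(1:6, length.out = 100)))
  n1 <- sample_negatives(p, 500, seed = 9)
  n2 <- sample_negatives(p, 500, seed = 9)
  expect_identical(n1, n2)
  comp <- setNames(p$compartment, p$id)
  expect_true(all(comp[n1$idA] != comp[n1$idB]))
  expect_true(all(n1$idA != n1$idB))
  key <- paste(pmin(n1$idA, n1$idB), pmax(n1$idA, n1$idB))
  expect_identical(anyDuplicated(key), 0L)
  # a supplied positive set is never re-drawn as a negative
  pos <- n1[1:50, c("idA", "idB")]
  pos$label <- 1L
  n3 <- sample_negatives(p, 500, seed = 10, positives = pos)
  key3 <- paste(pmin(n3$idA, n3$idB), pmax(n3$idA, n3$idB))
  keyp <- paste(pmin(pos$idA, pos$idB), pmax(pos$idA, pos$idB))
  expect_length(intersect(key3, keyp), 0L)
  expect_error(sample_negatives(protein_set("a", "ACDEF", "x"), 1, 1),
               "two distinct compartments")
})

test_that("alignment identity matches an independent Gotoh implementation", {
  expect_identical(pairwise_identity("MREIVHIQAGWK", "MREIVHIQAGWK"), 1)
  expect_identical(pairwise_identity(strrep("A", 8), strrep("C", 8)), 0)
  expect_error(pairwise_identity("", "AAA"), "empty")
  sm <- blosum62_matrix()
  set.seed(21)
  for (r in 1:8) {
    a <- random_protein(60)
    b <- random_protein(60)
    oracle <- gotoh_align(a, b, sm)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-12)
    # co-optimal tracebacks may differ slightly in match count, so the
    # identity is compared with an absolute band around the oracle's
    expect_lt(abs(pairwise_identity(a, b) - oracle$identity), 0.05)
  }
})

test_that("redundancy filtering removes planted homologs and nothing else", {
  set.seed(22)
  train <- protein_set(c("t1", "t2"),
                       c(random_protein(100), random_protein(100)))
  shared <- substr(train$seq[1], 1, 45)     # 45 identical leading residues
  homolog <- paste0(shared, random_protein(55))
  test_prot <- protein_set(
    c("h1", "r1", "r2", "r3"),
    c(homolog, random_protein(100), random_protein(100), random_protein(100))
  )
  pairs <- data.frame(idA = c("h1", "r1", "r3"), idB = c("r2", "r2", "r1"),
                      label = c(1L, 0L, 1L))
  res <- remove_redundant(pairs, test_prot, train, threshold = 0.3)
  expect_identical(res$kept$idA, c("r1", "r3"))
  expect_identical(nrow(res$removed), 1L)
  expect_identical(res$removed$test_id, "h1")
  expect_identical(res$removed$train_id, "t1")
  expect_gte(res$removed$identity, 0.3)
  # a test pair duplicating a training protein is removed at identity 1
  dup_pairs <- data.frame(idA = "d", idB = "r1", label = 1L)
  dup_prot <- protein_set(c("d", "r1"), c(train$seq[1], test_prot$seq[2]))
  res2 <- remove_redundant(dup_pairs, dup_prot, train, threshold = 0.25)
  expect_identical(nrow(res2$kept), 0L)
  expect_equal(res2$removed$identity, 1)
  # an unreachable threshold removes nothing
  res3 <- remove_redundant(pairs, test_prot, train, threshold = 1.01)
  expect_identical(nrow(res3$removed), 0L)
})

test_that("raising the identity threshold never removes more pairs", {
  set.seed(23)
  train <- protein_set("t1", random_protein(80))
  test_prot <- protein_set(paste0("x", 1:6),
                           replicate(6, random_protein(80)))
  pairs <- data.frame(idA = paste0("x", 1:3), idB = paste0("x", 4:6),
                      label = 1L)
  removed <- vapply(c(0.05, 0.15, 0.5, 0.9), function(thr)
    nrow(remove_redundant(pairs, test_prot, train, threshold = thr)$removed),
    numeric(1))
  expect_true(all(diff(removed) <= 0))
})

test_that("stratified folds partition the data with balanced labels", {
  labels <- rep(c(0L, 1L), each = 50)
  fold <- make_folds(labels, k = 10, seed = 3)
  expect_identical(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 10))
  # stratification: per-fold positives within one of the global rate
  per_fold_pos <- tapply(labels, fold, sum)
  expect_true(all(abs(per_fold_pos - 5) <= 1))
  expect_identical(make_folds(labels, 10, seed = 3),
                   make_folds(labels, 10, seed = 3))
  # unbalanced sizes still differ by at most one
  fold2 <- make_folds(rep(c(0L, 1L), c(13, 10)), k = 4, seed = 1)
  expect_lte(diff(range(table(fold2))), 1L)
  expect_error(make_folds(c(0L, 1L), k = 3), "exceeds")
  expect_error(make_folds(labels, k = 1), "at least 2")
})

test_that("hold-out splitting conserves and separates samples", {
  samples <- data.frame(idA = paste0("a", 1:100), idB = paste0("b", 1:100),
                        label = rep(0:1, 50))
  spl <- holdout_split(samples, 20, seed = 4)
  expect_identical(nrow(spl$train), 80L)
  expect_identical(nrow(spl$holdout), 20L)
  expect_length(intersect(rownames(spl$train), rownames(spl$holdout)), 0L)
  pooled <- rbind(spl$train, spl$holdout)
  expect_identical(sort(pooled$idA), sort(samples$idA))
  expect_identical(holdout_split(samples, 20, seed = 4)$holdout$idA,
                   spl$holdout$idA)
  expect_error(holdout_split(samples, 0, seed = 1), "positive")
  expect_error(holdout_split(samples, 100, seed = 1), "smaller")
})
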