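test_that("k-mer profiles record presence of every distinct substring", {
  kp <- kmer_profile(c(a = "AAA"), 3)
  expect_equal(sum(kp$matrix), 1)
  expect_equal(unname(kp$matrix[1, "AAA"]), 1L)

  kp2 <- kmer_profile(c(a = "ACGU"), 3)
  expect_equal(sort(colnames(kp2$matrix)[kp2$matrix[1, ] == 1]),
               c("ACG", "CGT"))

  seqs <- generate_sequences(10, c(26, 31), seed = 4)
  kp3 <- kmer_profile(seqs, 3)
  # substring-set oracle
  for (i in seq_along(seqs)) {
    s <- chartr("U", "T", seqs[[i]])
    expected <- length(unique(substring(s, 1:(nchar(s) - 2), 3:nchar(s))))
    expect_equal(sum(kp3$matrix[i, ]), expected)
  }
  expect_error(kmer_profile(c(x = "ACGN")), "x")
})

test_that("Jaccard similarity equals the hand count and brute-force loop", {
  x <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(1, 1, 0))
  s <- jaccard_similarity(x)
  expect_equal(s["a", "b"], 1 / 3)
  expect_equal(s["a", "c"], 1)
  expect_equal(max(abs(s - t(s))), 0)

  y <- rbind(c(1, 0), c(0, 1))
  expect_equal(jaccard_similarity(y)[1, 2], 0)
  expect_error(jaccard_similarity(rbind(c(1, 0), c(0, 0))), "all-zero")

  p <- random_profiles(12, 8, seed = 2)
  p[rowSums(p) == 0, 1] <- 1
  s2 <- jaccard_similarity(p)
  for (i in 1:12) for (j in 1:12) {
    expect_equal(s2[i, j],
                 sum(p[i, ] & p[j, ]) / sum(p[i, ] | p[j, ]),
                 info = paste(i, j))
  }
})

test_that("GIP kernel matches direct substitution and a brute-force loop", {
  p <- rbind(c(1, 0), c(0, 1))
  s <- gip_similarity(p)  # mean squared norm 1 -> gamma 1, distance^2 = 2
  expect_equal(s[1, 2], exp(-2))
  expect_equal(diag(s), c(1, 1))

  prof <- random_profiles(10, 5, seed = 6)
  prof[rowSums(prof) == 0, 1] <- 1
  s2 <- gip_similarity(prof)
  gamma <- 1 / mean(rowSums(prof^2))
  for (i in 1:10) for (j in 1:10) {
    expect_equal(s2[i, j],
                 if (i == j) 1 else exp(-gamma * sum((prof[i, ] - prof[j, ])^2)))
  }
  expect_error(gip_similarity(matrix(0, 3, 3)), "bandwidth")
})

test_that("similarity integration keeps primary values and halves GIP fallback", {
  prim <- matrix(c(1, 0.4, 0.4, 1), 2)
  gip <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(integrate_piRNA_similarity(prim, gip)[1, 2], 0.4)
  prim0 <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(integrate_piRNA_similarity(prim0, gip)[1, 2], 0.3)
  expect_equal(integrate_disease_similarity(prim0,
                                            matrix(c(1, 0.8, 0.8, 1), 2))[1, 2], 0.4)
  expect_error(integrate_piRNA_similarity(prim, matrix(1, 3, 3)), "shape")

  with_seed(3, {
    a <- matrix(runif(25) * rbinom(25, 1, 0.5), 5); a <- (a + t(a)) / 2; diag(a) <- 1
    g <- matrix(runif(25), 5); g <- (g + t(g)) / 2; diag(g) <- 1
  })
  out <- integrate_piRNA_similarity(a, g)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(out[i, j],
                 if (i == j) 1 else if (a[i, j] != 0) a[i, j] else g[i, j] / 2)
  }
  # coverage never decreases: zero output only where both inputs are zero
  expect_true(all(out[a == 0 & g != 0] != 0))
})

test_that("tree numbers expand to prefix-chain ancestor sets", {
  dag <- build_disease_dag(tree_numbers = data.frame(d = "dz1", t = "C04.588"))
  expect_setequal(dag$ancestors$dz1, c("C04", "C04.588"))
  dag2 <- build_disease_dag(tree_numbers = data.frame(
    d = c("a", "b"), t = c("C04.588", "C04.557")))
  expect_true("C04" %in% intersect(dag2$ancestors$a, dag2$ancestors$b))

  # reachability oracle on a toy DAG given as explicit edges
  edges <- data.frame(child = c("b", "c", "d", "d"),
                      parent = c("a", "a", "b", "c"))
  dag3 <- build_disease_dag(parent_edges = edges)
  reach <- function(x) {
    out <- x
    repeat {
      nxt <- unique(c(out, edges$parent[edges$child %in% out]))
      if (length(nxt) == length(out)) return(out)
      out <- nxt
    }
  }
  for (d in c("a", "b", "c", "d")) {
    expect_setequal(dag3$ancestors[[d]], reach(d))
  }
  expect_error(
    build_disease_dag(parent_edges = data.frame(child = c("a", "b"),
                                                parent = c("b", "a"))),
    "cycle")
})

test_that("semantic contributions decay by 0.5 per hop with max over paths", {
  chain <- build_disease_dag(tree_numbers = data.frame(d = "x", t = "A.1"))
  ct <- semantic_contribution(chain, "x")
  expect_equal(unname(ct["A.1"]), 1)
  expect_equal(unname(ct["A"]), 0.5)

  # diamond: two paths of lengths 2 and 3 from the disease up to the apex
  dag <- build_disease_dag(parent_edges = data.frame(
    child = c("d", "d", "mid", "top2", "top"),
    parent = c("mid", "top2", "top", "topmost", "topmost")))
  ct2 <- semantic_contribution(dag, "d")
  expect_equal(unname(ct2["topmost"]), max(0.25, 0.125))
})

test_that("semantic values accumulate along chains", {
  # isolated disease via tree number with no dots
  iso2 <- build_disease_dag(tree_numbers = data.frame(d = "solo", t = "Z9"))
  expect_equal(semantic_value(iso2, "solo"), 1)
  two <- build_disease_dag(tree_numbers = data.frame(d = "x", t = "A.1"))
  expect_equal(semantic_value(two, "x"), 1.5)
  three <- build_disease_dag(tree_numbers = data.frame(d = "x", t = "A.1.2"))
  expect_equal(semantic_value(three, "x"), 1.75)
})

test_that("semantic similarity is 1 on self, 0 on disjoint, 1/3 for root siblings", {
  dag <- build_disease_dag(tree_numbers = data.frame(
    d = c("a", "b", "c"), t = c("R.1", "R.2", "Q.1")))
  expect_equal(semantic_similarity(dag, "a", "a"), 1)
  expect_equal(semantic_similarity(dag, "a", "b"), 1 / 3)
  expect_equal(semantic_similarity(dag, "a", "c"), 0)
  expect_equal(semantic_similarity(dag, "a", "b"),
               semantic_similarity(dag, "b", "a"))
  m <- semantic_similarity_matrix(dag, c("a", "b", "c"))
  expect_equal(m["a", "b"], 1 / 3)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
})

test_that("similarity matrices are symmetric with unit diagonal in [0, 1]", {
  fx <- generate_fixture(benchmark_spec(31))
  assoc <- fx$assoc
  SJ <- jaccard_similarity(kmer_profile(fx$sequences))
  SPG <- gip_similarity(assoc$A_pd)
  dag <- build_disease_dag(tree_numbers = fx$tree_numbers)
  Ssem <- semantic_similarity_matrix(dag, assoc$disease_ids)
  SDG <- gip_similarity(t(assoc$A_pd))
  for (S in list(SJ, SPG, Ssem, SDG,
                 integrate_piRNA_similarity(SJ, SPG),
                 integrate_disease_similarity(Ssem, SDG))) {
    expect_lt(max(abs(S - t(S))), 1e-9)
    expect_equal(max(abs(diag(S) - 1)), 0)
    expect_true(all(S >= 0 & S <= 1))
  }
})

test_that("FASTA round-trip preserves ids and sequences", {
  seqs <- generate_sequences(5, c(26, 31), seed = 9)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
})
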