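test_that("neighbor joining recovers additive quartets exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:4):0);")
  dm <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  nj <- nj_tree(dm)
  back <- ape::cophenetic.phylo(nj)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(back, dm, tolerance = 1e-12)
  # sister structure preserved
  expect_equal(sort(ls_quartet(dm)$topology), c("A", "B"))
})

test_that("neighbor joining matches the least-squares quartet oracle", {
  set.seed(51)
  for (i in 1:200) {
    q <- random_additive_quartet()   # true cherries (a,b) | (c,d)
    nj <- nj_tree(q$dm)
    ls <- ls_quartet(q$dm)
    expect_equal(sort(ls$topology), c("a", "b"))
    # a's sister when rooted at d must be b
    rt <- ape::root(nj, outgroup = "d", resolve.root = TRUE)
    ai <- match("a", rt$tip.label)
    parent <- rt$edge[match(ai, rt$edge[, 2]), 1]
    expect_equal(setdiff(tips_under_test(rt, parent), "a"), "b")
    # additive input: branch lengths reproduce distances exactly
    expect_equal(ape::cophenetic.phylo(nj)[rownames(q$dm), colnames(q$dm)],
                 q$dm, tolerance = 1e-9)
  }
})

test_that("equal distances collapse to a star with a zero internal edge", {
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  nj <- nj_tree(dm)
  expect_true(all(nj$edge.length >= 0))
  back <- ape::cophenetic.phylo(nj)[letters[1:4], letters[1:4]]
  # internal edge 0: all path lengths equal tip sums
  internal <- nj$edge[, 2] > length(nj$tip.label)
  expect_true(all(nj$edge.length[internal] < 1e-12))
})

test_that("in-house NJ agrees with the reference implementation", {
  set.seed(52)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    pts <- matrix(runif(n * 3), ncol = 3)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- nj_tree(dm)
    ref <- ape::nj(as.dist(dm))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("window extraction tiles scaffolds at the configured stride", {
  set.seed(53)
  L <- 250000
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  g <- list(blue1 = c(sc1 = s), sable1 = c(sc1 = s))
  w <- extract_windows(g, window_config(window_size = 20000, gap = 80000))
  expect_equal(w$start, c(1L, 100001L, 200001L))
  expect_equal(w$end, c(20000L, 120000L, 220000L))
  expect_equal(unique(w$end - w$start + 1L), 20000L)

  # window count formula for L >= w, several configurations
  for (cfg in list(c(20000, 80000), c(7000, 0), c(9999, 1))) {
    wc <- window_config(window_size = cfg[1], gap = cfg[2])
    got <- nrow(extract_windows(g, wc))
    expect_equal(got, floor((L - cfg[1]) / (cfg[1] + cfg[2])) + 1)
  }
})

test_that("windows with too much missing data are dropped", {
  a <- strrep("ACGT", 500)                 # 2000 bp
  b <- paste0(strrep("N", 1200), substr(a, 1201, 2000))  # 60% N
  g <- list(x = c(s = a), y = c(s = b))
  w05 <- extract_windows(g, window_config(window_size = 2000, gap = 0,
                                          missing_threshold = 0.5))
  expect_equal(nrow(w05), 0)
  w07 <- extract_windows(g, window_config(window_size = 2000, gap = 0,
                                          missing_threshold = 0.7))
  expect_equal(nrow(w07), 1)
  # scaffold shorter than the window yields nothing
  short <- list(x = c(s = "ACGT"), y = c(s = "ACGT"))
  expect_equal(nrow(extract_windows(short,
                                    window_config(window_size = 10))), 0)
})

test_that("transversion distances see through transitions", {
  expect_equal(transversion_distance("ACGT", "ACGT")$distance, 0)
  expect_equal(transversion_distance("ACGT", "GTAC")$distance, 0)
  expect_equal(transversion_distance("AAAA", "TTTT")$distance, 1)
  d <- transversion_distance("ANCT", "AACA")
  expect_equal(d$n_comparable, 3)          # pairwise deletion drops site 2
  expect_equal(d$distance, 1 / 3)          # only T/A at site 4 counts
  expect_error(transversion_distance("AC", "A"), "length")
})

test_that("topology classification handles all quartet resolutions", {
  bs <- ape::read.tree(text = "((blue:1,sable:1):1,(roan:1,outgroup:1):1);")
  expect_equal(classify_topology(bs), "BS")
  br <- ape::read.tree(text = "((blue:1,roan:1):1,(sable:1,outgroup:1):1);")
  expect_equal(classify_topology(br), "BR")
  rs <- ape::read.tree(text = "((roan:1,sable:1):1,(blue:1,outgroup:1):1);")
  expect_equal(classify_topology(rs), "RS")
  tiny <- ape::read.tree(
    text = "((blue:1,roan:1):0.0000001,(sable:1,outgroup:1):1);")
  expect_equal(classify_topology(tiny, tol = 1e-5), "other")
  expect_error(classify_topology(ape::read.tree(text = "((a:1,b:1):1,c:1);")),
               "roles")
})

test_that("five-taxon trees separate nested from sister attachment", {
  sister <- ape::read.tree(
    text = "(((roan1:1,roan2:1):1,blue1:2):1,(sable1:1,outgroup:1):1);")
  expect_equal(classify_topology(sister), "BR")
  nested <- ape::read.tree(
    text = "(((roan1:1,blue1:1):1,roan2:2):1,(sable1:1,outgroup:1):1);")
  expect_equal(classify_topology(nested), "BR_nested")
  tc <- timing_classification(c("BR", "BR", "BR_nested", "BS", "other"))
  expect_equal(tc$n, c(2L, 1L, 2L))
  expect_equal(sum(tc$fraction), 1)
})

test_that("topology summaries are proportions that sum to one", {
  s <- topology_summary(c(rep("BS", 5), rep("BR", 3), rep("RS", 2)))
  expect_equal(s$proportion, c(0.5, 0.3, 0.2, 0))
  expect_equal(sum(s$proportion), 1)
  expect_equal(topology_summary(rep("BS", 4))$proportion, c(1, 0, 0, 0))
  expect_error(topology_summary(character(0)), "no window")
})

test_that("site concordance counts decisive transversion patterns", {
  # all decisive sites support blue+sable
  m1 <- site_matrix(rbind(blue = c("A", "A", "C"),
                          sable = c("A", "A", "C"),
                          roan = c("T", "T", "G"),
                          outgroup = c("T", "T", "G")))
  expect_equal(site_concordance(m1)$sCF, 1)
  # one site per pattern: concordant, and the two discordant ones
  m2 <- site_matrix(rbind(blue = c("A", "A", "A"),
                          sable = c("A", "T", "T"),
                          roan = c("T", "A", "T"),
                          outgroup = c("T", "T", "A")))
  sc <- site_concordance(m2)
  expect_equal(sc$n_decisive, 3)
  expect_equal(sc$sCF, 1 / 3)
  # hand-built 12-column toy: 3 decisive sites, 2 concordant
  m3 <- site_matrix(rbind(
    blue = c("A", "A", "C", "G", "T", "A", "C", "N", "A", "A", "C", "T"),
    sable = c("A", "A", "C", "G", "T", "A", "C", "A", "T", "A", "C", "T"),
    roan = c("A", "G", "T", "G", "T", "A", "A", "A", "T", "A", "G", "A"),
    outgroup = c("A", "G", "T", "G", "C", "A", "A", "A", "A", "C", "C", "A")
  ))
  sc3 <- site_concordance(m3)
  expect_equal(sc3$n_decisive, 3)
  expect_equal(sc3$sCF, 2 / 3)
  expect_error(site_concordance(m1[1:3, ]), "4 taxa")
})

test_that("window trees on simulated data separate the topology classes", {
  ws <- window_study(f = 0, n_windows = 120, window_length = 10000,
                     rng_seed = 54, pop_size = 60000)
  expect_true(all(c("newick", "topology_class", "rs_path_proportion") %in%
                    names(ws)))
  s <- topology_summary(ws)
  expect_equal(sum(s$proportion), 1)
  p_bs <- s$proportion[s$topology_class == "BS"]
  expect_gt(p_bs, s$proportion[s$topology_class == "BR"])
  # without gene flow the two discordant classes stay balanced
  p_br <- s$proportion[s$topology_class == "BR"]
  p_rs <- s$proportion[s$topology_class == "RS"]
  expect_lt(abs(p_br - p_rs), 3 * sqrt((p_br + p_rs) / nrow(ws)) + 1e-9)
})
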