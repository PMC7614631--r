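test_that("greedy perfect phylogeny reproduces the caterpillar example", {
  m <- cbind(vAB = c(TRUE, TRUE, FALSE), vA = c(TRUE, FALSE, FALSE),
             vB = c(FALSE, TRUE, FALSE))
  rownames(m) <- c("A", "B", "C")
  phy <- build_tree(m)
  expect_length(phy$parked, 0)
  ## ((A,B),C): A and B share a parent distinct from the root
  expect_equal(phy$parent[1], phy$parent[2])
  expect_true(phy$parent[1] != phy$parent[3])
  expect_equal(phy$branch_count[1:3], c(1L, 1L, 0L))
  expect_equal(phy$branch_count[phy$parent[1]], 1L)
})

test_that("tree building is idempotent and recovers simulated topologies", {
  co <- fixture("reads_dft1")
  m <- truth_mutation_matrix(co)
  phy <- build_tree(m, dates = setNames(co$meta$sampling_date,
                                        co$meta$sample_id))
  expect_length(phy$parked, 0)  # compatible matrix: nothing conflicts
  skip_if_not_installed("phangorn")
  rf <- phangorn::RF.dist(ape::unroot(as_phylo(phy, "mutations")),
                          ape::unroot(as_phylo(co$tree, "years")))
  expect_equal(rf, 0)

  ## idempotence: rebuilding from the built tree's own variants returns it
  pres2 <- matrix(FALSE, phy$n_tip, sum(phy$branch_count),
                  dimnames = list(phy$tip_label,
                                  unlist(phy$branch_variants)))
  clades <- devilclones:::tree_clades(phy)
  for (v in seq_along(phy$branch_variants))
    pres2[clades[[v]], unlist(phy$branch_variants[v])] <- TRUE
  phy2 <- build_tree(pres2)
  rf2 <- phangorn::RF.dist(ape::unroot(as_phylo(phy, "mutations")),
                           ape::unroot(as_phylo(phy2, "mutations")))
  expect_equal(rf2, 0)
  expect_equal(sum(phy2$branch_count), sum(phy$branch_count))

  ## replicated recovery at high variant density
  hits <- 0L
  for (s in 1:10) {
    cfg <- dft1_config(n_tumours = 8, seed = 500 + s)
    cc <- simulate_cohort(cfg, detail = "variants", n_normals = 2)
    mm <- truth_mutation_matrix(cc)
    pp <- build_tree(mm)
    rf <- phangorn::RF.dist(ape::unroot(as_phylo(pp, "mutations")),
                            ape::unroot(as_phylo(cc$tree, "years")))
    hits <- hits + (rf == 0)
  }
  expect_gte(hits, 9L)
})

test_that("strict-clock posterior matches analytic and grid oracles", {
  ## single 10-year branch with 100 mutations: rate MLE = 10/yr
  tr <- manual_tree(c(3, 3, 0), c(2010, 2000, NA), c("A", "B"))
  tr$branch_count <- c(100L, 0L, 0L)
  class(tr) <- c("clone_phylogeny", "clone_tree")
  fit <- fit_strict_clock(tr, seed = 1, iterations = 20000, burn_in = 5000)
  expect_lt(abs(fit$rate["median"] - 10) / 10, 0.2)

  ## 3-tip tree: MCMC vs brute-force grid integration of the same posterior
  phy <- manual_tree(c(4, 5, 5, 0, 4), c(2014, 2016, 2018, NA, NA),
                     c("A", "B", "C"))
  phy$branch_count <- c(40L, 55L, 75L, 0L, 30L)
  class(phy) <- c("clone_phylogeny", "clone_tree")
  fit <- fit_strict_clock(phy, seed = 2, iterations = 60000, burn_in = 10000)

  ## independent oracle: grid over (r, t_root, t_int)
  r_gr <- seq(4, 22, length.out = 120)
  t4_gr <- seq(1990, 2013.99, length.out = 240)   # root
  t5_gr <- seq(1990, 2015.99, length.out = 260)   # internal (min tip 2016)
  ll <- array(-Inf, c(length(r_gr), length(t4_gr), length(t5_gr)))
  for (i in seq_along(r_gr)) for (j in seq_along(t4_gr)) {
    t4 <- t4_gr[j]
    valid <- t5_gr > t4
    if (!any(valid)) next
    r <- r_gr[i]
    d1 <- 2014 - t4; d5 <- t5_gr[valid] - t4
    d2 <- 2016 - t5_gr[valid]; d3 <- 2018 - t5_gr[valid]
    ll[i, j, valid] <-
      (40 * log(r * d1) - r * d1) +
      (30 * log(r * d5) - r * d5) +
      (55 * log(r * d2) - r * d2) +
      (75 * log(r * d3) - r * d3)
  }
  post <- exp(ll - max(ll, na.rm = TRUE))
  post[!is.finite(post)] <- 0
  pr <- apply(post, 1, sum); pr <- pr / sum(pr)
  p4 <- apply(post, 2, sum); p4 <- p4 / sum(p4)
  med_of <- function(grid, w) grid[which.min(abs(cumsum(w) - 0.5))]
  expect_lt(abs(fit$rate["median"] - med_of(r_gr, pr)), 0.5)
  expect_lt(abs(fit$root["median"] - med_of(t4_gr, p4)), 0.25)

  ## rescaling durations by c and the rate by 1/c leaves inference consistent
  phy_scaled <- phy
  phy_scaled$date <- c(2 * (phy$date[1:3] - 2000) + 2000, NA, NA)
  fit_s <- fit_strict_clock(phy_scaled, seed = 2, iterations = 30000,
                            burn_in = 5000)
  expect_lt(abs(fit_s$rate["median"] - fit$rate["median"] / 2) /
              (fit$rate["median"] / 2), 0.15)

  ## unidentifiable when all tips share a date
  tr2 <- manual_tree(c(3, 3, 0), c(2010, 2010, NA), c("A", "B"))
  tr2$branch_count <- c(10L, 10L, 0L)
  expect_error(fit_strict_clock(tr2), "unidentifiable")
})

test_that("origin ambiguity extends the root interval rootward", {
  phy <- manual_tree(c(4, 5, 5, 0, 4), c(2014, 2016, 2018, NA, NA),
                     c("A", "B", "C"))
  phy$branch_count <- c(40L, 55L, 75L, 0L, 30L)
  class(phy) <- c("clone_phylogeny", "clone_tree")
  fit <- fit_strict_clock(phy, seed = 3, iterations = 20000, burn_in = 4000)

  o0 <- origin_interval_with_ambiguity(fit, 0)
  expect_equal(o0$median, unname(fit$root["median"]))
  expect_equal(c(o0$lo, o0$hi), unname(fit$root[c("lo", "hi")]))

  ## fixed f: exact arithmetic r=500, shared=1000, f=0.5 -> 1 year
  fit_fixed <- fit
  fit_fixed$draws[, 1] <- 500
  of <- origin_interval_with_ambiguity(fit_fixed, 1000, f = 0.5)
  expect_equal(of$median, unname(quantile(fit$draws[, 5], 0.5)) - 1.0)

  ## interval width grows monotonically with the shared count
  widths <- vapply(c(0, 200, 600, 1500), function(sc) {
    o <- origin_interval_with_ambiguity(fit, sc, seed = 9)
    o$hi - o$lo
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("polytomy detection collapses only short internal branches", {
  ## strictly bifurcating, long branches: nothing reported
  tr <- manual_tree(c(4, 5, 5, 0, 4), c(2014, 2016, 2018, 2000, 2008),
                    c("A", "B", "C"))
  expect_equal(nrow(detect_polytomies(tr)), 0)
  expect_equal(nrow(detect_polytomies(tr, epsilon_years = 0)), 0)

  ## 6-way polytomy at the root built from near-zero internal branches
  cfg <- dft1_config(n_tumours = 6, multifurcation_prob = 1, seed = 4)
  tr6 <- simulate_transmission_tree(cfg)
  rep6 <- detect_polytomies(tr6, epsilon_years = 0.25)
  expect_equal(rep6$out_degree[rep6$node == 7], 6L)

  ## epsilon = 0 never collapses
  short <- manual_tree(c(4, 5, 5, 0, 4), c(2014, 2016, 2018, 2000, 2000.01),
                       c("A", "B", "C"))
  expect_equal(nrow(detect_polytomies(short, epsilon_years = 0)), 0)
  expect_equal(detect_polytomies(short, epsilon_years = 0.25)$out_degree, 3L)
})

test_that("irreversible parsimony counts event origins correctly", {
  co <- fixture("reads_dft1")
  tr <- co$tree
  clades <- devilclones:::tree_clades(tr)
  ## a full clade has a single origin at its stem
  v <- which(lengths(clades) >= 2 & lengths(clades) < tr$n_tip)[1]
  org <- map_event_to_tree(tr, tr$tip_label[clades[[v]]], "gain")
  expect_equal(org, v)
  ## two tips in different clades: two origins
  pair <- c(clades[[v]][1], setdiff(seq_len(tr$n_tip), clades[[v]])[1])
  expect_length(map_event_to_tree(tr, tr$tip_label[pair], "loss"), 2)
  expect_error(map_event_to_tree(tr, character()), "carrier")

  ## five planted loss branches (one whole clade + four scattered tips whose
  ## parents are all distinct) are recovered as exactly five origins
  cfg <- dft2_config(n_tumours = 30, seed = 88)
  tr30 <- simulate_transmission_tree(cfg)
  cl30 <- devilclones:::tree_clades(tr30)
  sizes <- lengths(cl30)
  vint <- which(seq_along(sizes) > tr30$n_tip + 1 & sizes >= 3 &
                  sizes <= tr30$n_tip - 10)[1]
  picked <- vint
  used_parents <- tr30$parent[vint]
  for (tip in setdiff(seq_len(tr30$n_tip), cl30[[vint]])) {
    if (length(picked) == 5) break
    if (!(tr30$parent[tip] %in% used_parents)) {
      picked <- c(picked, tip)
      used_parents <- c(used_parents, tr30$parent[tip])
    }
  }
  carriers <- tr30$tip_label[unlist(cl30[picked])]
  expect_setequal(map_event_to_tree(tr30, carriers, "loss"), sort(picked))
})
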