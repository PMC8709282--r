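mk_atc <- function(...) {
  codes <- list(...)
  atc_table(data.frame(
    drug_id = rep(names(codes), lengths(codes)),
    atc_code = unlist(codes, use.names = FALSE)))
}

test_that("cluster histograms count drugs once per letter", {
  atc <- mk_atc(d1 = "N01AB01", d2 = c("N02AA01", "C01AA01"))
  h <- cluster_histogram(c("d1", "d2"), atc)
  expect_equal(h$letters, c(N = 2L, C = 1L))

  # two N codes on one drug still contribute 1 to N
  atc2 <- mk_atc(d1 = c("N01AB01", "N05BA01"))
  expect_equal(cluster_histogram("d1", atc2)$letters, c(N = 1L))

  # drugs without codes are tallied apart
  h3 <- cluster_histogram(c("d1", "ghost1", "ghost2"), atc)
  expect_equal(h3$n_no_atc, 2)
  h4 <- cluster_histogram(c("ghost1", "ghost2"), atc)
  expect_equal(length(h4$letters), 0)
  expect_equal(h4$n_no_atc, 2)
})

test_that("dominant property: unique maximum, ties, top-k, empty error", {
  atc <- mk_atc(a = "N01AB01", b = "N01AB02", c = "R03AC02")
  h <- cluster_histogram(c("a", "b", "c"), atc)
  expect_equal(dominant_property(h), "N")
  expect_equal(dominant_property(h, k = 2), c("N", "R"))

  tie <- mk_atc(a = "G03AA01", b = "G03AA02", c = "G03AA03",
                d = "C01AA01", e = "C01AA02", f = "C01AA03")
  ht <- cluster_histogram(letters[1:6], tie)
  expect_equal(dominant_property(ht), "C")  # alphabetical tie-break

  empty <- cluster_histogram(c("x", "y"), mk_atc(z = "N01AB01"))
  expect_error(dominant_property(empty), "no dominant")
})

test_that("confirmation requires the letter to be new, not already held", {
  # cluster 0 dominated by G; t1 gains G in the new table, t2 already has G,
  # t3 never gains it, t4 is absent from the new table entirely
  part <- ddsn_partition(stats::setNames(
    rep(0L, 6), c("g1", "g2", "g3", "t1", "t2", "t3")))
  old <- mk_atc(g1 = "G03AA01", g2 = "G03AA02", g3 = "G03AA03",
                t1 = "C03CA04", t2 = c("C01AA01", "G04BD07"), t3 = "N01AB01")
  new <- mk_atc(g1 = "G03AA01", g2 = "G03AA02", g3 = "G03AA03",
                t1 = c("C03CA04", "G04BD07"), t2 = c("C01AA01", "G04BD07"),
                t3 = "N01AB01")
  cs <- confirmed_repositionings(part, old, new)
  expect_equal(cs$n, 1)
  expect_equal(cs$records$drug_id, "t1")
  expect_equal(cs$records$predicted_letter, "G")

  # absent from the new table: second condition fails on the empty set
  part2 <- ddsn_partition(stats::setNames(rep(0L, 4), c("g1", "g2", "g3", "t4")))
  old2 <- mk_atc(g1 = "G03AA01", g2 = "G03AA02", g3 = "G03AA03",
                 t4 = "C03CA04")
  new2 <- mk_atc(g1 = "G03AA01", g2 = "G03AA02", g3 = "G03AA03")
  expect_equal(confirmed_repositionings(part2, old2, new2)$n, 0)
})

test_that("confirmed records satisfy both set conditions against raw tables", {
  b <- generate_fixture(fixture_spec(seed = 21))
  g <- records_to_ddsn(b$interactions$records)
  p <- louvain_cluster(g, resolution = 2, seed = 4, restarts = 2)
  cs <- confirmed_repositionings(p, b$atc_old, b$atc_new)
  expect_gt(cs$n, 0)
  for (r in seq_len(cs$n)) {
    d <- cs$records$drug_id[r]
    letter <- cs$records$predicted_letter[r]
    old_letters <- extract_atc_level1(atc_codes_for(b$atc_old, d))
    new_letters <- extract_atc_level1(atc_codes_for(b$atc_new, d))
    expect_false(letter %in% old_letters)
    expect_true(letter %in% new_letters)
  }
})

test_that("granting the dominant letter never decreases the confirmed count", {
  part <- ddsn_partition(stats::setNames(rep(0L, 5), c("a", "b", "e", "c", "d")))
  old <- mk_atc(a = "N01AB01", b = "N01AB02", e = "N05BA01",
                c = "C01AA01", d = "C01AA02")
  new0 <- old
  new1 <- mk_atc(a = "N01AB01", b = "N01AB02", e = "N05BA01",
                 c = c("C01AA01", "N02BA01"), d = "C01AA02")
  new2 <- mk_atc(a = "N01AB01", b = "N01AB02", e = "N05BA01",
                 c = c("C01AA01", "N02BA01"), d = c("C01AA02", "N02BA01"))
  n0 <- confirmed_repositionings(part, old, new0)$n
  n1 <- confirmed_repositionings(part, old, new1)$n
  n2 <- confirmed_repositionings(part, old, new2)$n
  expect_true(n0 <= n1 && n1 <= n2)
  expect_equal(c(n0, n1, n2), c(0, 1, 2))
})

test_that("hints list exactly the drugs missing the dominant letter", {
  part <- ddsn_partition(stats::setNames(rep(0L, 3), c("n1", "n2", "c1")))
  atc <- mk_atc(n1 = "N01AB01", n2 = "N02AA01", c1 = "C01AA01")
  h <- hints_from_partition(part, atc)
  expect_equal(nrow(h), 1)
  expect_equal(h$drug_id, "c1")
  expect_equal(h$predicted_letter, "N")
  expect_false(h$no_current_atc)

  # every drug already carries the dominant letter: no hints
  all_n <- mk_atc(n1 = "N01AB01", n2 = "N02AA01", c1 = c("C01AA01", "N05BA01"))
  expect_equal(nrow(hints_from_partition(part, all_n)), 0)

  # drugs without ATC codes are eligible recipients and flagged
  part2 <- ddsn_partition(stats::setNames(rep(0L, 3), c("n1", "n2", "nude")))
  h2 <- hints_from_partition(part2, atc)
  expect_equal(h2$drug_id, "nude")
  expect_true(h2$no_current_atc)

  # singleton cluster whose only drug defines the dominant letter: no hints
  solo <- ddsn_partition(stats::setNames(c(0L, 1L, 1L), c("n1", "n2", "c1")))
  h3 <- hints_from_partition(solo, atc)
  expect_false("n1" %in% h3$drug_id)
})

test_that("no hint ever predicts a letter the drug already holds", {
  b <- generate_fixture(fixture_spec(seed = 33))
  g <- records_to_ddsn(b$interactions$records)
  hints <- generate_hints(g, 2, b$atc_old, seed = 3, restarts = 2)
  sets <- lapply(hints$drug_id, function(d)
    extract_atc_level1(atc_codes_for(b$atc_old, d)))
  expect_false(any(mapply(function(p, s) p %in% s,
                          hints$predicted_letter, sets)))
})

test_that("tuning reports the largest resolution among ties and 1-point grids", {
  b <- generate_fixture(fixture_spec())
  g <- records_to_ddsn(b$interactions$records)
  sw1 <- tune_resolution(g, b$atc_old, b$atc_new, grid = 1.5,
                         seed = 42, restarts = 1)
  expect_equal(sw1$lambda_max, 1.5)
  expect_equal(nrow(sw1$sweep), 1)

  sw <- tune_resolution(g, b$atc_old, b$atc_new, grid = c(1.0, 2.0),
                        seed = 42, restarts = 2)
  mx <- max(sw$sweep$n_confirmed)
  expect_equal(sw$lambda_max, max(sw$sweep$lambda[sw$sweep$n_confirmed == mx]))
  expect_equal(sw$best$n, mx)
})

test_that("candidate ranking follows betweenness, degree, then id", {
  # star cluster: the hinted center ranks first
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  igraph::E(star)$weight <- 1
  cen <- centralities(star)
  hints <- tibble::tibble(
    drug_id = c("hub", "l1", "l2"), cluster = 0L,
    current_level1 = "C", predicted_letter = "N", no_current_atc = FALSE)
  ranked <- rank_candidates(hints, cen)
  expect_equal(ranked$drug_id[1], "hub")
  expect_equal(ranked$rank, 1:3)

  # all-zero betweenness clique: degree then id decide
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("b", "a", "c")
  igraph::E(k3)$weight <- c(5, 5, 1)  # (b,a) (b,c) (a,c)
  cen3 <- centralities(k3)
  hints3 <- tibble::tibble(drug_id = c("a", "b", "c"), cluster = 0L,
                           current_level1 = "", predicted_letter = "N",
                           no_current_atc = TRUE)
  ranked3 <- rank_candidates(hints3, cen3)
  expect_equal(ranked3$drug_id, c("b", "a", "c"))  # deg 10 > 6 > 6, then id

  expect_error(rank_candidates(hints3, cen), "no centrality")
})

test_that("ranking matches an independent sort and truncates per cluster", {
  set.seed(8)
  g <- records_to_ddsn(random_records(18, 8, 3, 80, seed = 8))
  cen <- centralities(g)
  hints <- tibble::tibble(
    drug_id = cen$drug_id,
    cluster = rep(0:1, length.out = nrow(cen)),
    current_level1 = "C", predicted_letter = "N", no_current_atc = FALSE)
  ranked <- rank_candidates(hints, cen, top_n = 3)
  expect_true(all(table(ranked$cluster) <= 3))
  # independent re-sort of the documented key
  full <- rank_candidates(hints, cen, top_n = Inf)
  o <- with(full, order(cluster, -betweenness, -degree, drug_id))
  expect_equal(full$drug_id, full$drug_id[o])
})
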