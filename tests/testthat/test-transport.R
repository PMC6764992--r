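path_net <- function(n = 3L) {
  g <- sprintf("g%d", seq_len(n))
  gene_network(data.frame(from = g[-n], to = g[-1L]), nodes = g)
}

test_that("to_distribution normalizes per component", {
  g2 <- path_net(2L)
  d <- to_distribution(c(g1 = 2, g2 = 2), g2)
  expect_equal(unname(d$masses[[1]]), c(0.5, 0.5))

  # two components {A,B}, {C}: per-component normalization
  net <- gene_network(data.frame(from = "A", to = "B"), nodes = c("A", "B", "C"))
  d2 <- to_distribution(c(A = 1, B = 0, C = 3), net)
  expect_equal(unname(d2$masses[[1]]), c(1, 0))
  expect_equal(unname(d2$masses[[2]]), 1)

  expect_error(to_distribution(c(A = 0, B = 0, C = 3), net),
               "empty component")
  d3 <- to_distribution(c(A = 0, B = 0, C = 3), net, on_empty = "flag")
  expect_true(d3$empty[1])
})

test_that("invariant measure is the stationary law of the expression-attracted walk", {
  tri <- gene_network(data.frame(from = c("A", "A", "B"),
                                 to = c("B", "C", "C")))
  x <- c(A = 1, B = 1, C = 2)
  d <- to_distribution(x, tri, mode = "invariant_measure")
  pi_ <- d$masses[[1]]
  # oracle: power-iterate the lazy transition matrix built literally
  P <- rbind(c(0, 1 / 3, 2 / 3), c(1 / 3, 0, 2 / 3), c(1 / 2, 1 / 2, 0))
  P <- 0.5 * diag(3) + 0.5 * P
  expect_equal(unname(pi_), power_stationary(P), tolerance = 1e-10)
  # stationarity of the package's own output
  expect_equal(as.vector(pi_ %*% P), unname(pi_), tolerance = 1e-8)
})

test_that("invariant measure is strictly positive with a pseudocount", {
  net <- path_net(4L)
  d <- to_distribution(c(g1 = 0, g2 = 5, g3 = 0, g4 = 1), net,
                       mode = "invariant_measure", pseudocount = 0.1)
  expect_true(all(d$masses[[1]] > 0))
  expect_equal(sum(d$masses[[1]]), 1, tolerance = 1e-9)
})

test_that("emd_component matches hand values on paths and stars", {
  gm <- ground_metric(path_net(3L))[[1]]
  expect_equal(emd_component(c(1, 0, 0), c(0, 0, 1), gm), 2)
  expect_equal(emd_component(c(0.5, 0.5, 0), c(0, 0.5, 0.5), gm), 1)
  p <- c(0.2, 0.5, 0.3)
  expect_equal(emd_component(p, p, gm), 0)
  # star: center g1, three leaves; uniform on leaves -> all mass to center
  g <- c("c", "l1", "l2", "l3")
  star <- gene_network(data.frame(from = "c", to = g[-1]), nodes = g)
  gs <- ground_metric(star)[[1]]
  expect_equal(emd_component(c(0, 1, 1, 1) / 3, c(1, 0, 0, 0), gs), 1)
})

test_that("emd_component validates masses", {
  gm <- ground_metric(path_net(3L))[[1]]
  expect_error(emd_component(c(1, 0, 0), c(0, 0, 0.5), gm), "differ")
  expect_error(emd_component(c(-0.5, 1.5, 0), c(0, 0, 1), gm), "negative")
})

test_that("emd_component agrees with the LP oracle on random instances", {
  skip_if_not_installed("boot")
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    C <- random_connected_metric(n)
    p <- runif(n); p <- p / sum(p)
    q <- runif(n); q <- q / sum(q)
    expect_equal(emd_component(p, q, C), lp_transport_oracle(p, q, C),
                 tolerance = 1e-8)
  }
})

test_that("on unit paths emd_component equals the CDF closed form", {
  set.seed(102)
  for (rep in 1:30) {
    n <- sample(3:9, 1)
    gm <- ground_metric(path_net(n))[[1]]
    p <- runif(n); p <- p / sum(p)
    q <- runif(n); q <- q / sum(q)
    expect_equal(emd_component(p, q, gm), cdf_path_emd(p, q),
                 tolerance = 1e-12)
  }
})

test_that("emd never exceeds the component diameter", {
  set.seed(103)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    C <- random_connected_metric(n)
    p <- runif(n); p <- p / sum(p)
    q <- runif(n); q <- q / sum(q)
    expect_lte(emd_component(p, q, C), max(C) + 1e-12)
  }
})

test_that("Hungarian quantization converges to the exact LP value", {
  skip_if_not_installed("clue")
  set.seed(104)
  gm <- ground_metric(path_net(5L))[[1]]
  p <- runif(5); p <- p / sum(p)
  q <- runif(5); q <- q / sum(q)
  exact <- emd_component(p, q, gm)
  # quantization error shrinks like 1/K; K = 2000 should land within ~2%
  expect_equal(emd_hungarian(p, q, gm, K = 2000L), exact, tolerance = 2e-2)
  expect_lt(abs(emd_hungarian(p, q, gm, K = 2000L) - exact),
            abs(emd_hungarian(p, q, gm, K = 100L) - exact) + 5e-3)
})

test_that("sample_distance amalgamates components by root sum of squares", {
  # two path components engineered to give per-component EMDs 3 and 4
  g <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4", "b5")
  net <- gene_network(data.frame(from = c("a1", "a2", "a3", "b1", "b2", "b3", "b4"),
                                 to = c("a2", "a3", "a4", "b2", "b3", "b4", "b5")),
                      nodes = g)
  gm <- ground_metric(net)
  a <- to_distribution(c(a1 = 1, a2 = 0, a3 = 0, a4 = 0,
                         b1 = 1, b2 = 0, b3 = 0, b4 = 0, b5 = 0), net)
  b <- to_distribution(c(a1 = 0, a2 = 0, a3 = 0, a4 = 1,
                         b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 1), net)
  expect_equal(emd_component(a$masses[[1]], b$masses[[1]], gm[[1]]), 3)
  expect_equal(emd_component(a$masses[[2]], b$masses[[2]], gm[[2]]), 4)
  expect_equal(sample_distance(a, b, gm), 5)
  expect_equal(sample_distance(a, a, gm), 0)
})

test_that("empty components: both empty contribute 0, one empty errors", {
  net <- gene_network(data.frame(from = "A", to = "B"),
                      nodes = c("A", "B", "C", "D"))
  # C and D are isolated singleton components
  gm <- ground_metric(net)
  a <- to_distribution(c(A = 1, B = 1, C = 0, D = 2), net, on_empty = "flag")
  b <- to_distribution(c(A = 2, B = 0, C = 0, D = 1), net, on_empty = "flag")
  expect_equal(sample_distance(a, b, gm), 0.5)   # only component {A,B} moves
  cc <- to_distribution(c(A = 1, B = 1, C = 3, D = 1), net, on_empty = "flag")
  expect_error(sample_distance(a, cc, gm), "incomparable")
})

test_that("sample_distance satisfies metric axioms on random triples", {
  set.seed(105)
  net <- gene_network(data.frame(from = c("A", "B", "C", "C"),
                                 to = c("B", "C", "D", "E")))
  gm <- ground_metric(net)
  for (rep in 1:30) {
    xs <- lapply(1:3, function(i)
      to_distribution(setNames(runif(5, 0.1, 2), network_nodes(net)), net))
    d12 <- sample_distance(xs[[1]], xs[[2]], gm)
    d13 <- sample_distance(xs[[1]], xs[[3]], gm)
    d23 <- sample_distance(xs[[2]], xs[[3]], gm)
    expect_equal(d12, sample_distance(xs[[2]], xs[[1]], gm))
    expect_gte(d12, 0)
    expect_lte(d13, d12 + d23 + 1e-8)
  }
})

test_that("distance_matrix handles degenerate and identical samples", {
  net <- path_net(3L)
  one <- expr_matrix(matrix(c(1, 2, 3), 3, 1,
                            dimnames = list(network_nodes(net), "s1")), "raw")
  D1 <- distance_matrix(one, net)
  expect_equal(unclass(D1), matrix(0, 1, 1, dimnames = list("s1", "s1")))
  two <- expr_matrix(matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
                            dimnames = list(network_nodes(net), c("s1", "s2"))), "raw")
  D2 <- distance_matrix(two, net)
  expect_equal(D2["s1", "s2"], 0)
  # errors name the offending sample
  zero <- expr_matrix(matrix(c(0, 0, 0, 1, 2, 3), 3, 2,
                             dimnames = list(network_nodes(net), c("bad", "ok"))), "raw")
  expect_error(distance_matrix(zero, net), "bad")
})

test_that("near-supported samples are Wasserstein-closer despite equal Euclidean gaps", {
  demo <- location_contrast_demo()
  D <- distance_matrix(demo$expression, demo$network)
  v <- unclass(demo$expression)
  eu <- as.matrix(dist(t(v)))
  expect_equal(eu[demo$near[1], demo$near[2]], eu[demo$far[1], demo$far[2]])
  expect_lt(D[demo$near[1], demo$near[2]], D[demo$far[1], demo$far[2]])
})
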