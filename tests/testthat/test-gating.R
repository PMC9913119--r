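test_that("histograms conserve counts and locate the distribution", {
  tab <- data.frame(v = rep(3.5, 10))
  h <- make_histogram(tab, "v", bins = 5)
  expect_equal(sum(h$counts), 10)
  expect_equal(sum(h$counts > 0), 1)

  set.seed(1)
  tab2 <- data.frame(dna = rnorm(5000, 100, 10))
  h2 <- make_histogram(tab2, "dna", bins = 64)
  expect_equal(sum(h2$counts), 5000)
  mode_at <- h2$mids[which.max(h2$counts)]
  bw <- diff(h2$edges[1:2])
  expect_lt(abs(mode_at - 100), 2 * bw)

  expect_error(make_histogram(data.frame(v = c(1, -1)), "v",
                              transform = "log10"),
               class = "transform_error")
  expect_error(make_histogram(tab, "nope"), class = "parameter_error")
})

test_that("geometric and boolean gates agree with per-event evaluation", {
  set.seed(2)
  tab <- data.frame(x = runif(1000, 0, 10), y = runif(1000, 0, 10))
  g <- list(
    gate_rect("left", c("x", "y"), c(0, 5), c(0, 10)),
    gate_rect("low", c("x", "y"), c(0, 10), c(0, 5)),
    gate_rect("all", c("x", "y"), c(0, 10), c(0, 10)),
    gate_boolean("both", "AND", c("left", "low")),
    gate_boolean("either", "OR", c("left", "low")),
    gate_boolean("none", "NOT", "all"))
  res <- apply_gates(tab, g)
  manual <- tab$x <= 5 & tab$y <= 5
  expect_equal(unname(res$membership[, "both"]), manual)
  expect_equal(unname(res$membership[, "either"]), tab$x <= 5 | tab$y <= 5)
  expect_equal(sum(res$membership[, "all"]), 1000)
  expect_equal(sum(res$membership[, "none"]), 0)
  expect_equal(res$stats$pct_total[res$stats$gate == "all"], 100)

  # polygon gate vs half-plane: triangle over the lower-left half
  gp <- gate_polygon("tri", c("x", "y"),
                     rbind(c(0, 0), c(10, 0), c(0, 10)))
  mp <- apply_gates(tab, list(gp))$membership[, 1]
  expect_equal(unname(mp), tab$x + tab$y <= 10)
  expect_error(gate_polygon("bad", c("x", "y"),
                            rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               class = "validation_error")
  expect_error(apply_gates(tab, list(gate_boolean("b", "AND", "ghost"))),
               class = "configuration_error")
})

test_that("gate algebra obeys De Morgan's laws", {
  set.seed(3)
  tab <- data.frame(x = rnorm(500), y = rnorm(500))
  g <- list(
    gate_range("a", "x", -1, 1),
    gate_range("b", "y", 0, 3),
    gate_boolean("and_ab", "AND", c("a", "b")),
    gate_boolean("or_ab", "OR", c("a", "b")),
    gate_boolean("not_a", "NOT", "a"),
    gate_boolean("not_b", "NOT", "b"),
    gate_boolean("not_and", "NOT", "and_ab"),
    gate_boolean("not_or", "NOT", "or_ab"),
    gate_boolean("demorgan1", "OR", c("not_a", "not_b")),
    gate_boolean("demorgan2", "AND", c("not_a", "not_b")))
  m <- apply_gates(tab, g)$membership
  expect_equal(m[, "not_and"], m[, "demorgan1"])
  expect_equal(m[, "not_or"], m[, "demorgan2"])
})

test_that("population statistics report counts, percents and means", {
  tab <- data.frame(x = c(1, 2, 3, 4), y = c(10, 20, 30, 40))
  g <- list(gate_range("lo", "x", 0, 2.5),
            gate_range("hi", "x", 2.5, 5, parent = "lo"))
  st <- apply_gates(tab, g)$stats
  expect_equal(st$count, c(2, 2))
  expect_equal(st$pct_total, c(50, 50))
  expect_equal(st$pct_parent[2], 100)  # parent has 2 events, gate has 2
  expect_equal(st$mean_y, c(15, 35))
})

test_that("cell-cycle classification recovers phantom truth in both modes", {
  pop <- generate_population(phantom_config(population = list(n_cells = 600)),
                             seed = 31)
  res <- run_cytometry(pop)
  mi <- match_cells_to_truth(res$cells, pop$truth)
  truth_phase <- pop$truth$phase[mi]
  for (mode in c("edu", "dna")) {
    lab <- classify_cell_cycle(res$cells, cell_cycle_config(mode = mode))
    for (ph in c("G1", "S", "G2", "M")) {
      sel <- !is.na(truth_phase) & truth_phase == ph
      expect_gte(mean(lab$phase[sel] == ph), 0.9)
    }
  }
})

test_that("classification rules evaluate as specified on constructed cells", {
  # population of G1 cells at exactly the peak, plus one clear mitotic cell
  n <- 300
  tab <- data.frame(cell_id = seq_len(n + 1),
                    dna_integrated = c(rnorm(n, 1000, 30), 2000),
                    dna_mean = c(rep(10, n), 40),
                    edu_mean = rep(1, n + 1),
                    area_um2 = c(rep(50, n), 20),
                    circularity = c(rep(0.85, n), 0.98),
                    marker_mean = rep(1, n + 1))
  lab <- classify_cell_cycle(tab, cell_cycle_config(
    mode = "dna", marker_threshold = NA))
  expect_true(all(lab$phase[seq_len(n)] == "G1"))
  # DNA = 2P, area 0.5 median, circularity 0.98: mitotic under defaults
  expect_equal(lab$phase[n + 1], "M")
  # same cell without condensation stays G2
  tab2 <- tab; tab2$dna_mean[n + 1] <- 10
  lab2 <- classify_cell_cycle(tab2, cell_cycle_config(
    mode = "dna", marker_threshold = NA))
  expect_equal(lab2$phase[n + 1], "G2")
  # all cells at the peak, EdU negative: all G1 in EdU mode
  lab3 <- classify_cell_cycle(tab[seq_len(n), ],
                              cell_cycle_config(mode = "edu",
                                                edu_threshold = 5,
                                                marker_threshold = NA))
  expect_true(all(lab3$phase == "G1"))
})

test_that("classification is invariant to uniform DNA rescaling", {
  pop <- generate_population(phantom_config(population = list(n_cells = 400)),
                             seed = 32)
  res <- run_cytometry(pop)
  lab1 <- classify_cell_cycle(res$cells, cell_cycle_config(mode = "dna"))
  scaled <- res$cells
  scaled$dna_integrated <- scaled$dna_integrated * 37.3
  scaled$dna_mean <- scaled$dna_mean * 37.3
  lab2 <- classify_cell_cycle(scaled, cell_cycle_config(mode = "dna"))
  expect_equal(lab1$phase, lab2$phase)
  # phase labels partition the classified set
  counts <- table(factor(lab1$phase,
                         c("G1", "S", "G2", "M", "unclassified")))
  expect_equal(sum(counts), nrow(res$cells))
  # peakless input errors
  expect_error(classify_cell_cycle(data.frame(dna_integrated = rep(1, 5)),
                                   cell_cycle_config(mode = "dna")),
               class = "classification_error")
})

test_that("event selection is deterministic and respects gates and phases", {
  tab <- data.frame(cell_id = c(3, 1, 2), source_file = c("b", "a", "a"),
                    x = c(5, 1, 9))
  ids <- select_events(tab, membership = tab$x > 2)
  expect_equal(ids, c(2, 3))          # ordered by source file then id
  labels <- data.frame(cell_id = c(3, 1, 2), phase = c("M", "G1", "M"))
  expect_equal(select_events(tab, labels = labels, phase = "M"), c(2, 3))
  expect_equal(select_events(tab, membership = rep(FALSE, 3)), numeric(0))
  # disjoint gates give disjoint selections
  a <- select_events(tab, membership = tab$x < 2)
  b <- select_events(tab, membership = tab$x >= 2)
  expect_length(intersect(a, b), 0)
})
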