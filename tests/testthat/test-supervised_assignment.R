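test_that("matching score counts multi-label members toward every class", {
  labels <- list(J1 = 1L, J2 = 1L, J3 = 1L, J4 = 2L, J5 = 3L)
  ms <- matching_score(paste0("J", 1:5), labels)
  expect_equal(ms$score, 0.6)
  expect_equal(ms$classes, 1L)

  ms2 <- matching_score(c("J1", "J2"), list(J1 = 1L, J2 = 1L))
  expect_equal(ms2$score, 1)

  # tie through multi-label members
  ms3 <- matching_score(c("A", "B"), list(A = c(1L, 2L), B = c(1L, 2L)))
  expect_equal(ms3$score, 1)
  expect_equal(ms3$classes, c(1L, 2L))

  # unlabeled members dilute the denominator only
  ms4 <- matching_score(c("A", "B"), list(A = 1L, B = integer(0)))
  expect_equal(ms4$score, 0.5)

  # single-label corpora: per-class counts sum to cluster size
  set.seed(9)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    labs <- lapply(sample(1:4, n, replace = TRUE), identity)
    names(labs) <- sprintf("F%02d", 1:n)
    counts <- table(unlist(labs))
    expect_equal(sum(counts), n)
    expect_equal(matching_score(names(labs), labs)$score, max(counts) / n)
  }
})

test_that("disease assignment is strict and voids ties", {
  labels <- list(J1 = 1L, J2 = 1L, J3 = 1L, J4 = 2L, J5 = 3L)
  cl <- list(cluster_id = "C1", members = paste0("J", 1:5))
  # score exactly at the threshold does not qualify
  expect_false(assign_disease(cl, labels, threshold = 0.6)$qualified)
  a <- assign_disease(cl, labels, threshold = 0.5)
  expect_true(a$qualified)
  expect_equal(a$dominant_class, 1L)

  tie <- list(cluster_id = "C2", members = c("A", "B"))
  at <- assign_disease(tie, list(A = c(1L, 2L), B = c(1L, 2L)), threshold = 0.6)
  expect_false(at$qualified)
  expect_true(is.na(at$dominant_class))
})

test_that("dominant plants return all ties and handle empty ingredients", {
  ds <- toy_dataset()
  expect_equal(dominant_plants(c("J1", "J2", "J3"), ds), "p1")
  expect_equal(dominant_plants(c("J1", "J2"), ds), c("p1", "p2"))
  expect_error(dominant_plants("nope", ds), "not in dataset")

  inc <- matrix(0L, 2, 2, dimnames = list(c("E1", "E2"), c("p1", "p2")))
  empty_ds <- formula_dataset(inc)
  expect_length(dominant_plants(c("E1", "E2"), empty_ds), 0)
})

test_that("relation prediction pools qualified clusters, order-invariantly", {
  sim <- generate_formulas(synthetic_spec(p_sig = 1, p_bg = 0, seed = 5))
  frac <- 5 * choose(30, 2) / choose(150, 2)
  res <- run_pipeline(sim$dataset, pipeline_config(top_fraction = frac))
  rel <- res$prediction$relations
  # every predicted pair is a planted (signature plant, class) pair
  truth_key <- paste(sim$truth$pairs$plant_id, sim$truth$pairs$class_id)
  expect_true(all(paste(rel$plant_id, rel$class_id) %in% truth_key))
  expect_setequal(paste(rel$plant_id, rel$class_id), truth_key)

  # dominant plant frequency equals cluster size when p_sig = 1
  for (cl in res$filtered$clusters) {
    freq <- colSums(sim$dataset$incidence[cl$members, , drop = FALSE])
    expect_equal(max(freq), cl$size)
  }

  # cluster order invariance
  cs <- res$filtered
  rev_cs <- structure(list(clusters = rev(cs$clusters), coverage = cs$coverage),
                      class = "cluster_set")
  rel2 <- predict_relations(rev_cs, sim$dataset, threshold = 0.6)$relations
  expect_identical(rel[c("plant_id", "class_id", "support")],
                   rel2[c("plant_id", "class_id", "support")])

  # no qualified clusters -> empty prediction (unlabeled corpus scores 0)
  blank <- lapply(sim$dataset$labels, function(x) integer(0))
  none <- predict_relations(cs, sim$dataset, labels = blank,
                            threshold = 0.6)$relations
  expect_equal(nrow(none), 0)
})

test_that("success-rate curve is monotone with correct point values", {
  mk <- function(scores) {
    cls <- lapply(seq_along(scores), function(k) {
      n <- 20
      good <- round(scores[k] * n)
      labs <- c(rep(1L, good), seq(2L, length.out = n - good))
      list(cluster_id = paste0("C", k),
           members = sprintf("F%d_%02d", k, 1:n), size = n,
           labels = labs)
    })
    labels <- do.call(c, lapply(cls, function(cl) {
      l <- lapply(cl$labels, identity); names(l) <- cl$members; l
    }))
    list(cs = structure(list(clusters = cls, coverage = list()),
                        class = "cluster_set"),
         labels = labels)
  }
  x <- mk(c(0.5, 0.7, 0.95))
  out <- success_rate_curve(x$cs, x$labels, thresholds = c(0.4, 0.6, 0.9))
  expect_equal(out$curve$success_rate, c(3, 2, 1) / 3)
  expect_equal(sum(out$histogram$count), 3)

  y <- mk(rep(1, 4))
  oy <- success_rate_curve(y$cs, y$labels, thresholds = seq(0.1, 0.9, 0.1))
  expect_true(all(oy$curve$success_rate == 1))

  # monotone non-increasing for any cluster set
  set.seed(14)
  z <- mk(runif(10))
  oz <- success_rate_curve(z$cs, z$labels, thresholds = seq(0.05, 0.95, 0.05))
  expect_true(all(diff(oz$curve$success_rate) <= 0))
  expect_true(all(oz$curve$success_rate >= 0 & oz$curve$success_rate <= 1))
})

test_that("plant-class multiplicity histogram matches the printed list", {
  printed <- load_printed_predictions()
  rel <- data.frame(plant_id = printed$plant, class_id = printed$class_id)
  m <- plant_class_multiplicity(rel)
  expect_equal(m$n_plants, 135L)
  expect_equal(m$n_single, 63L)
  expect_equal(m$n_multi, 72L)
  expect_equal(sum(m$table$n_plants), 135L)

  empty <- plant_class_multiplicity(data.frame(plant_id = character(0),
                                               class_id = integer(0)))
  expect_equal(empty$n_plants, 0L)
})
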