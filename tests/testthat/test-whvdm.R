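test_that("conditional probabilities follow the add-alpha counting formula", {
  cb <- case_base(data.frame(attr = c("a", "a")), y = c("pos", "neg"))
  tab0 <- estimate_cond_probs(cb, alpha = 0)
  expect_equal(unname(tab0$tables$attr["a", ]), c(0.5, 0.5))
  # alpha = 1, value seen once with class pos, |Y| = 2 -> 2/3
  cb2 <- case_base(data.frame(attr = c("a", "b")), y = c("pos", "neg"))
  tab1 <- estimate_cond_probs(cb2, alpha = 1)
  expect_equal(tab1$tables$attr["a", "pos"], 2 / 3)
  # unseen value is uniform
  expect_equal(unname(cbrmatch:::cond_dist(tab1, "attr", "zzz")), c(0.5, 0.5))
  expect_true(all(abs(rowSums(tab1$tables$attr) - 1) < 1e-12))
  expect_error(estimate_cond_probs(case_base(data.frame(a = numeric(0)))), "empty")
})

test_that("vdm_component matches the hand-enumerated toy values", {
  tb <- toy_vdm_base()
  tab <- estimate_cond_probs(tb, alpha = 0)
  t_a <- get_case(tb, 1)  # value a
  r_b <- get_case(tb, 5)  # value b
  expect_equal(vdm_component("attr", t_a, r_b, tab, "classic"), 0.5)
  expect_equal(vdm_component("attr", t_a, r_b, tab, "as_printed"), 0.25)
  expect_equal(vdm_component("attr", t_a, get_case(tb, 2), tab, "classic"), 0)
  # classic is symmetric; as_printed is not
  expect_equal(vdm_component("attr", r_b, t_a, tab, "classic"), 0.5)
  expect_equal(vdm_component("attr", r_b, t_a, tab, "as_printed"), 0.5)
  expect_false(isTRUE(all.equal(
    vdm_component("attr", t_a, r_b, tab, "as_printed"),
    vdm_component("attr", r_b, t_a, tab, "as_printed"))))
  # missing value yields the penalty
  t_na <- new_case(attr = NA)
  expect_equal(vdm_component("attr", t_na, r_b, tab, missing_penalty = 0.7), 0.7)
  expect_error(vdm_component("age", t_a, r_b, tab, base = case_base(
    data.frame(attr = "a", age = 1), y = "pos")), "not discrete")
})

test_that("diff2_component is the squared normalized difference", {
  t1 <- new_case(v = 0.3); t2 <- new_case(v = 0.3)
  expect_equal(diff2_component("v", t1, t2), 0)
  expect_equal(diff2_component("v", new_case(v = 0), new_case(v = 1)), 1)
  expect_equal(diff2_component("v", new_case(v = 0.2), new_case(v = 0.5)), 0.09)
  expect_equal(diff2_component("v", new_case(v = NA), new_case(v = 0.5),
                               missing_penalty = 0.4), 0.4)
})

test_that("whvdm_distance combines weighted components and matches brute force", {
  # hand arithmetic: discrete d2 = 0.25, continuous d2 = 0.09, w = (.5, .5)
  tb <- toy_vdm_base()
  mixed <- case_base(data.frame(attr = tb$x$attr, v = c(0.2, 0.5, 0.1, 0.9, 0.4, 0.8)),
                     y = tb$y)
  tab <- estimate_cond_probs(mixed, alpha = 0)
  t <- new_case(attr = "a", v = 0.2)
  r <- new_case(attr = "b", v = 0.5)
  d <- whvdm_distance(t, r, c(0.5, 0.5), tab, distance_config(alpha = 0),
                      base = mixed)
  expect_equal(d, 0.5 * 0.25 + 0.5 * 0.09)
  expect_equal(whvdm_distance(t, t, c(0.5, 0.5), tab, base = mixed), 0)
  # brute-force agreement on random mixed bases (alpha = 0, classic)
  set.seed(23)
  gen <- gen_case_base(case_gen_spec(n_cases = 20, n_noise = 2, seed = 23))
  nb <- normalize_continuous(gen$base)$base
  tabr <- estimate_cond_probs(nb, alpha = 0)
  cfg <- distance_config("classic", alpha = 0)
  w <- uniform_weights(nrow(nb$schema))
  for (i in 1:20) {
    a <- sample(20, 1); b <- sample(20, 1)
    d_pkg <- whvdm_distance(get_case(nb, a), get_case(nb, b), w, tabr, cfg,
                            base = nb)
    d_brute <- brute_whvdm(as.list(nb$x[a, ]), as.list(nb$x[b, ]),
                           as.numeric(w), nb, alpha = 0, variant = "classic")
    expect_equal(d_pkg, d_brute, tolerance = 1e-12)
  }
})

test_that("upweighting a differing attribute never decreases the distance", {
  # t and r agree everywhere except on one continuous attribute, so the
  # distance is weight_j * d_j and must be non-decreasing in weight_j
  cb <- case_base(data.frame(attr = c("a", "a", "b", "b"),
                             v = c(0.1, 0.8, 0.3, 0.6)),
                  y = c("p", "q", "p", "q"))
  tab <- estimate_cond_probs(cb)
  cfg <- distance_config()
  t <- new_case(attr = "a", v = 0.1)
  r <- new_case(attr = "a", v = 0.8)
  prev <- -1
  for (up in c(0.1, 0.3, 0.6, 0.9)) {
    d <- whvdm_distance(t, r, c(1 - up, up), tab, cfg, base = cb)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("retrieval matches exhaustive sort with stable tie-breaks", {
  gen <- gen_case_base(case_gen_spec(n_cases = 50, seed = 8))
  nb <- normalize_continuous(gen$base)$base
  tab <- estimate_cond_probs(nb)
  cfg <- distance_config()
  w <- uniform_weights(nrow(nb$schema))
  t <- get_case(nb, 7)
  top <- retrieve_top_k(t, nb, w, tab, cfg, k = 50)
  d_all <- vapply(seq_len(50), function(i)
    whvdm_distance(t, get_case(nb, i), w, tab, cfg, base = nb), numeric(1))
  ord <- order(d_all, seq_along(d_all))
  expect_equal(top$i, ord)
  expect_equal(top$distance, d_all[ord], tolerance = 1e-12)
  # self-retrieval at distance zero
  expect_equal(retrieve_top_k(t, nb, w, tab, cfg, k = 1)$i, 7)
  expect_equal(retrieve_top_k(t, nb, w, tab, cfg, k = 1)$distance, 0)
  # equidistant cases: earlier-stored case first
  dup <- case_base(data.frame(a = c("x", "y", "y")), y = c("p", "q", "q"))
  tab2 <- estimate_cond_probs(dup)
  t2 <- get_case(dup, 1)
  r <- retrieve_top_k(t2, dup, weight_vector(1), tab2, cfg, k = 3)
  expect_equal(r$i[1:2], c(1, 2))
  expect_warning(retrieve_top_k(t2, dup, weight_vector(1), tab2, cfg, k = 9),
                 "exceeds base size")
})

test_that("predict_class is the 1-NN label and evaluate counts correctly", {
  gen <- gen_case_base(case_gen_spec(n_cases = 60, seed = 21))
  sp <- split_case_base(gen$base, 0.7, seed = 21)
  nr <- normalize_continuous(sp$reference)
  te <- apply_normalization(sp$test, nr$map)
  tab <- estimate_cond_probs(nr$base)
  w <- uniform_weights(nrow(gen$base$schema))
  cfg <- distance_config()
  t <- get_case(nr$base, 3)
  expect_equal(predict_class(t, nr$base, w, tab, cfg), nr$base$y[3])
  expect_equal(predict_class(t, nr$base, w, tab, cfg),
               retrieve_top_k(t, nr$base, w, tab, cfg, k = 1)$y[1])
  ev <- evaluate(sp$reference, sp$test, w, cfg)
  # accuracy equals the hand count over per-case predictions
  by_hand <- sum(vapply(seq_len(n_cases(te)), function(i)
    predict_class(get_case(te, i), nr$base, w, tab, cfg) == te$y[i],
    logical(1)))
  expect_equal(ev$n_correct, by_hand)
  expect_equal(ev$accuracy, by_hand / n_cases(te))
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_true(ev$f_value >= 0 && ev$f_value <= 1)
  # test identical to reference predicts perfectly
  ev_id <- evaluate(sp$reference, sp$reference, w, cfg)
  expect_equal(ev_id$accuracy, 1)
  expect_equal(ev_id$f_value, 1)
  expect_error(evaluate(sp$reference, sp$test[0], w, cfg), "empty test")
})

test_that("weight_vector enforces the simplex constraints", {
  expect_silent(weight_vector(c(0.3, 0.7)))
  expect_error(weight_vector(c(0.5, 0.6)), "sum to 1")
  expect_error(weight_vector(c(-0.1, 1.1)), "0, 1")
  expect_equal(as.numeric(uniform_weights(4)), rep(0.25, 4))
})
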