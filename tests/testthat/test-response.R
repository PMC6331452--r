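test_that("gate_trend recovers exact slopes on noiseless data", {
  tab <- make_table(days = c(4, 24), reps = 1,
                    gates = list(G4 = function(d) 3.1 +
                                   (46.5 - 3.1) / 20 * (d - 4),
                                 G6 = function(d) rep(12, length(d))))
  fit <- gate_trend(tab, "T", "G4")
  expect_equal(fit$k, (46.5 - 3.1) / 20, tolerance = 1e-12)  # 2.17 %/day
  expect_equal(gate_trend(tab, "T", "G6")$k, 0, tolerance = 1e-12)
  # machine-precision exactness on longer noiseless series
  tab2 <- make_table(gates = list(G1 = function(d) 5 + 0.9 * d))
  expect_equal(gate_trend(tab2, "T", "G1")$k, 0.9, tolerance = 1e-10)
  expect_error(gate_trend(make_table(days = c(7, 8)), "T", "G1",
                          window = c(7, 7.5)), "distinct days")
})

test_that("window excludes the day-0 inoculum by default", {
  tab <- make_table(days = c(0, 4, 14, 24), reps = 1,
                    gates = list(G1 = function(d) ifelse(d == 0, 99,
                                                        10 + 0.5 * d)))
  fit <- gate_trend(tab, "T", "G1")
  expect_equal(fit$k, 0.5, tolerance = 1e-10)
  expect_equal(fit$n, 3)
})

test_that("slope CI covers the generative slope at the nominal rate", {
  hits <- 0L
  for (s in 1:200) {
    tab <- make_table(gates = list(G1 = function(d) 10 + 0.9 * d),
                      noise = 2, seed = s)
    fit <- gate_trend(tab, "T", "G1")
    if (fit$ci95[1] <= 0.9 && 0.9 <= fit$ci95[2]) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * 200 - 2 * sqrt(200 * 0.95 * 0.05))
})

test_that("spearman_response flags by the inclusive |rho| >= cutoff rule", {
  tab <- make_table(gates = list(G1 = function(d) 1 + d))
  sp <- spearman_response(tab, "T", "G1")
  expect_equal(sp$rho, 1)
  expect_true(sp$strong)
  # strictness at the boundary: a rho just below the cutoff is not strong
  tab2 <- make_table(gates = list(G1 = function(d) d %% 5), noise = 3,
                     seed = 4)
  r <- spearman_response(tab2, "T", "G1")$rho
  expect_true(spearman_response(tab2, "T", "G1",
                                cutoff = abs(r))$strong)
  expect_false(spearman_response(tab2, "T", "G1",
                                 cutoff = abs(r) + 1e-9)$strong)
  # zero-variance series: undefined rho, explicitly not strong
  flat <- make_table(gates = list(G1 = function(d) rep(5, length(d))))
  sp0 <- spearman_response(flat, "T", "G1")
  expect_identical(sp0$status, "undefined")
  expect_false(sp0$strong)
  expect_true(is.na(sp0$rho))
})

test_that("rho matches the average-rank oracle on tied small series", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:6, 1)
    day <- sort(sample(1:4, n, replace = TRUE))
    ab <- sample(1:3, n, replace = TRUE) + 0.5 * sample(0:1, n, TRUE)
    if (var(day) == 0 || var(ab) == 0) next
    tab <- data.frame(treatment = "T", replicate = 1, day = day,
                      G1 = ab, ungated = 0L, total = 1L)
    class(tab) <- c("abundance_table", "data.frame")
    sp <- spearman_response(tab, "T", "G1", window = range(day))
    expect_equal(sp$rho, brute_spearman(day, ab), tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  tab <- make_table(gates = list(G1 = function(d) 2 + 0.3 * d), noise = 1,
                    seed = 17)
  r0 <- spearman_response(tab, "T", "G1")$rho
  for (f in list(function(x) x^3, function(x) exp(x / 10),
                 function(x) log(x + 1))) {
    tab2 <- tab
    tab2$G1 <- f(tab$G1)
    expect_equal(spearman_response(tab2, "T", "G1")$rho, r0)
  }
})

test_that("raising the cutoff never adds flagged gates", {
  set.seed(19)
  tab <- make_table(gates = list(G1 = function(d) 30 + 0.5 * d,
                                 G2 = function(d) 40 - 0.3 * d,
                                 G3 = function(d) rep(30, length(d))),
                    noise = 4, seed = 19)
  flags <- function(cut) {
    rep <- response_report(tab, cutoff = cut)
    rep$gate[rep$strong]
  }
  prev <- flags(0.1)
  for (cut in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- flags(cut)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("marker classification follows the sign and floor rules", {
  tab <- make_table(gates = list(Gup = function(d) 5 + 1.0 * d,
                                 Gdown = function(d) 40 - 1.0 * d,
                                 Gtiny = function(d) pmax(0.5 - 0.02 * d, 0),
                                 Gflat = function(d) rep(20, length(d))),
                    noise = 0.5, seed = 23)
  rep <- response_report(tab)
  mk <- select_marker_gates(rep, "T")
  expect_setequal(mk$positive, "Gup")
  expect_setequal(mk$negative, "Gdown")   # Gtiny fails the 1% floor
  # all-flat table: no markers
  flat <- make_table(gates = list(G1 = function(d) rep(50, length(d)),
                                  G2 = function(d) rep(50, length(d))))
  mk0 <- select_marker_gates(response_report(flat), "T")
  expect_length(mk0$positive, 0)
  expect_length(mk0$negative, 0)
})

test_that("markers are reported per treatment, not filtered for specificity", {
  t1 <- make_table(gates = list(G1 = function(d) 5 + d,
                                G2 = function(d) 95 - d), treatment = "Neg")
  t2 <- make_table(gates = list(G1 = function(d) 5 + d,
                                G2 = function(d) 95 - d), treatment = "Tox")
  tab <- rbind(t1, t2)
  class(tab) <- c("abundance_table", "data.frame")
  rep <- response_report(tab)
  expect_setequal(select_marker_gates(rep, "Neg")$positive, "G1")
  expect_setequal(select_marker_gates(rep, "Tox")$positive, "G1")
})

test_that("fold_change reproduces the reported ratio and edge cases", {
  tab <- rbind(
    make_table(days = 24, reps = 3,
               gates = list(G4 = function(d) rep(31.3, length(d)),
                            G5 = function(d) rep(1, length(d))),
               treatment = "EC50Ag30"),
    make_table(days = 24, reps = 3,
               gates = list(G4 = function(d) rep(3.726, length(d)),
                            G5 = function(d) rep(0, length(d))),
               treatment = "Neg"))
  class(tab) <- c("abundance_table", "data.frame")
  fc <- fold_change(tab, "G4", "EC50Ag30", "Neg", 24)
  expect_equal(fc$fold, 8.4, tolerance = 0.001)
  expect_equal(fold_change(tab, "G4", "Neg", "Neg", 24)$fold, 1)
  inf <- fold_change(tab, "G5", "EC50Ag30", "Neg", 24)
  expect_identical(inf$status, "infinite")
  expect_identical(inf$fold, Inf)
})

test_that("cybar-scale slopes are available and labeled", {
  tab <- make_table(gates = list(G1 = function(d) 3.1 + 2.17 * (d - 4),
                                 G2 = function(d) 50 - 0.5 * d))
  raw <- gate_trend(tab, "T", "G1")
  cyb <- gate_trend(tab, "T", "G1", scale = "cybar")
  expect_identical(raw$scale, "percent")
  expect_identical(cyb$scale, "cybar")
  # min-max scaling maps the 20-day rise onto [0,1]: slope 1/20
  expect_equal(cyb$k, 1 / 20, tolerance = 1e-10)
})
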