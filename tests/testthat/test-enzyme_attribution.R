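test_that("the encoded pathway graph is a DAG covering the panel", {
  g <- steroidogenesis_graph()
  expect_true(igraph::is_dag(g))
  expect_true(all(steroid_analytes() %in% igraph::V(g)$name))
  expect_true(all(nzchar(igraph::edge_attr(g, "enzyme"))))
})

test_that("enzyme lookup follows pathway routes in either orientation", {
  g <- steroidogenesis_graph()
  expect_identical(enzymes_for_pair("progesterone", "17-OH-progesterone", g),
                   "P450C17")
  # argument order must not matter for a single step
  expect_identical(enzymes_for_pair("17-OH-progesterone", "progesterone", g),
                   "P450C17")
  expect_identical(enzymes_for_pair("DHEA", "DHEAS", g), "sulfotransferase")
  # multi-step route collects every enzyme along it
  expect_identical(enzymes_for_pair("progesterone", "aldosterone", g),
                   c("21-hydroxylase", "11b-hydroxylase",
                     "aldosterone-synthase"))
  # two branch endpoints have no directed route in either orientation
  expect_identical(enzymes_for_pair("aldosterone", "DHEAS", g), character(0))
  expect_error(enzymes_for_pair("cholestero", "DHEA", g), "not in pathway")
})

test_that("ratio separation ranking finds a planted discriminating pair", {
  set.seed(42)
  mk <- function(cls, n, shift) {
    do.call(rbind, lapply(seq_len(n), function(s) {
      p <- test_panel() * exp(rnorm(10, 0, 0.05))
      p["17-OH-progesterone"] <- p["17-OH-progesterone"] * shift
      data.frame(id = paste0(cls, s), class = cls, as.list(p),
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
  }
  co <- steroid_cohort(rbind(mk("PCa", 10, 4), mk("BPH", 10, 1),
                             mk("HC", 10, 1)))
  sc <- rank_ratio_separation(co)
  # every high-ranking pair involves the shifted steroid, and the planted
  # androstenedione pairing sits above the default selection threshold
  top <- sc[1, ]
  expect_true("17-OH-progesterone" %in% c(top$num, top$den))
  sel <- select_discriminative(sc, threshold = 40)
  expect_true(any(sel$num == "androstenedione" &
                    sel$den == "17-OH-progesterone"))
  expect_true(all(sel$coefficient > 40))
  # the planted substrate/product pair is attributed to its enzyme
  planted <- sel[sel$num == "androstenedione" &
                   sel$den == "17-OH-progesterone", ]
  expect_identical(planted$enzymes, "P450C17")

  # scores are invariant to globally rescaling any one subject's panel
  co2 <- co
  co2[7, steroid_analytes()] <- co2[7, steroid_analytes()] * 9
  expect_equal(rank_ratio_separation(co2), sc)
})

test_that("selection is monotone in threshold with sane extremes", {
  co <- toy_cohort(5, seed = 3)
  sc <- rank_ratio_separation(co)
  expect_true(all(sc$coefficient >= 1 & sc$coefficient <= 100))

  key <- function(df) paste(df$num, df$den)
  lo <- select_discriminative(sc, threshold = 20)
  hi <- select_discriminative(sc, threshold = 60)
  expect_true(all(key(hi) %in% key(lo)))
  expect_equal(nrow(select_discriminative(sc, threshold = 100)), 0L)
  expect_equal(nrow(select_discriminative(sc, threshold = 0)), 45L)
  # enzyme annotations only ever use labels present in the graph
  g <- steroidogenesis_graph()
  labs <- unlist(strsplit(lo$enzymes[nzchar(lo$enzymes)], ";"))
  expect_true(all(labs %in% igraph::edge_attr(g, "enzyme")))
})

test_that("identical class distributions collapse to the minimal score", {
  p <- test_panel()
  rows <- do.call(rbind, lapply(1:9, function(s) {
    data.frame(id = paste0("S", s), class = c("PCa", "BPH", "HC")[1 + s %% 3],
               as.list(p), check.names = FALSE, stringsAsFactors = FALSE)
  }))
  sc <- rank_ratio_separation(steroid_cohort(rows))
  expect_equal(sc$coefficient, rep(1, 45))
})
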