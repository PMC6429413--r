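# Active-site closure distances, O...P approach geometry and the NAC census.

# Minimal 5-atom site: Mg, NE2, nucleophile O, P, leaving O.
siteToy <- function() {
  s <- Structure(data.frame(
    name = c("MG", "NE2", "O3", "PG", "O3B"),
    element = c("MG", "N", "O", "P", "O"),
    resid = c(901L, 221L, 903L, 902L, 902L),
    resname = c("MG", "HIS", "DHA", "ATP", "ATP"),
    chain = c("B", "A", "A", "B", "B")),
    rbind(c(0, 0, 0), c(10, 0, 0), c(9, 1, 0), c(1, 1, 0), c(-0.6, 1, 0)))
  site <- siteDefinition(s, "L2-K1", closurePair = c(1L, 2L),
                         nucleophileOxygens = c(O3 = 3L),
                         gammaPhosphorus = 4L, leavingOxygen = 5L)
  list(s = s, site = site)
}

trajFromFrames <- function(s, frames, times = NULL) {
  Trajectory(s, t(vapply(frames, function(x) as.vector(t(x)),
                         numeric(3 * nAtoms(s)))), times = times)
}

test_that("closure series tracks the marker distance exactly", {
  st <- siteToy()
  tr <- trajFromFrames(st$s, list(coords(st$s), coords(st$s)))
  expect_equal(seriesValues(closureSeries(tr, st$site)), c(10, 10))
  # planted linear approach 14 -> 4 over the trajectory
  ramp <- seq(14, 4, length.out = 21)
  frames <- lapply(ramp, function(d) {
    x <- coords(st$s); x[2, ] <- c(d, 0, 0); x
  })
  ser <- closureSeries(trajFromFrames(st$s, frames), st$site)
  expect_equal(seriesValues(ser), ramp, tolerance = 1e-6)
  one <- closureSeries(trajFromFrames(st$s, frames[1]), st$site)
  expect_length(seriesValues(one), 1L)
})

test_that("O...P distances and in-line angles follow exact constructions", {
  st <- siteToy()
  place <- function(o, p, l) {
    x <- coords(st$s); x[3, ] <- o; x[4, ] <- p; x[5, ] <- l
    trajFromFrames(st$s, list(x))
  }
  # boundary distance 3.5 A
  tr <- place(c(0, 0, 0), c(3.5, 0, 0), c(5.1, 0, 0))
  expect_equal(seriesValues(opDistanceSeries(tr, st$site, "O3")), 3.5)
  expect_error(opDistanceSeries(tr, st$site, "O9"), "unknown oxygen")
  expect_warning(opDistanceSeries(place(c(1, 1, 0), c(1, 1, 0), c(2, 1, 0)),
                                  st$site, "O3"), "coincident")
  # collinear with P between the oxygens: 180 degrees
  expect_equal(seriesValues(opoAngleSeries(tr, st$site, "O3")), 180)
  # right angle
  tr90 <- place(c(0, 2, 0), c(0, 0, 0), c(3, 0, 0))
  expect_equal(seriesValues(opoAngleSeries(tr90, st$site, "O3")), 90)
  # arbitrary constructed angle
  th <- 37.3 * pi / 180
  trth <- place(2.4 * c(cos(th), sin(th), 0), c(0, 0, 0), c(1.6, 0, 0))
  expect_equal(seriesValues(opoAngleSeries(trth, st$site, "O3")), 37.3,
               tolerance = 1e-6)
  expect_error(opoAngleSeries(place(c(0, 2, 0), c(0, 0, 0), c(0, 0, 0)),
                              st$site, "O3"), "zero-length")
})

test_that("geometry series are invariant under per-frame rigid transforms", {
  st <- siteToy()
  set.seed(141)
  frames <- lapply(1:6, function(i) coords(st$s) +
                     matrix(rnorm(15, sd = 0.3), 5, 3))
  tr <- trajFromFrames(st$s, frames)
  d0 <- seriesValues(opDistanceSeries(tr, st$site, "O3"))
  a0 <- seriesValues(opoAngleSeries(tr, st$site, "O3"))
  c0 <- seriesValues(closureSeries(tr, st$site))
  moved <- trajFromFrames(st$s, lapply(frames, function(x)
    applyRigid(x, randomRigid())))
  expect_equal(seriesValues(opDistanceSeries(moved, st$site, "O3")), d0,
               tolerance = 1e-9)
  expect_equal(seriesValues(opoAngleSeries(moved, st$site, "O3")), a0,
               tolerance = 1e-9)
  expect_equal(seriesValues(closureSeries(moved, st$site)), c0,
               tolerance = 1e-9)
})

test_that("the NAC filter applies strict cutoffs and counts planted coincidences", {
  mkser <- function(v, kind) new("GeometrySeries", times = seq_along(v),
                                 values = v, kind = kind)
  d <- mkser(c(3.16, 3.5, 3.49, 4.0, 2.9), "distance")
  a <- mkser(c(170, 178, 155, 170, 160), "angle")
  rec <- nacFilter(d, a)
  expect_equal(rec$passes, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_true(rec$vdw_contact[1])            # 3.16 < 3.3 and passing
  expect_true(rec$vdw_contact[5])            # 2.9 < 3.3 and passing
  expect_false(any(rec$vdw_contact[!rec$passes]))
  s <- nacSummary(rec)
  expect_equal(s$nPass, 2L)
  expect_equal(s$fraction, 0.4)
  expect_error(nacFilter(d, mkser(rep(160, 4), "angle")), "time grid")
  # planted census: exactly k coincident frames
  set.seed(151)
  dist <- runif(500, 3.6, 12)
  ang <- runif(500, 60, 150)
  hits <- sample(500, 17)
  dist[hits] <- runif(17, 2.9, 3.4); ang[hits] <- runif(17, 156, 179)
  expect_equal(nacSummary(nacFilter(mkser(dist, "distance"),
                                    mkser(ang, "angle")))$nPass, 17L)
})

test_that("relaxing either cutoff never decreases the passing count", {
  set.seed(161)
  d <- new("GeometrySeries", times = 1:400,
           values = runif(400, 2.5, 6), kind = "distance")
  a <- new("GeometrySeries", times = 1:400,
           values = runif(400, 120, 180), kind = "angle")
  counts <- outer(seq(3.0, 4.5, by = 0.25), seq(165, 140, by = -5),
                  Vectorize(function(dc, ac)
                    nacSummary(nacFilter(d, a, dCut = dc, aCut = ac))$nPass))
  expect_true(all(diff(counts) >= 0))        # wider distance cutoff
  expect_true(all(t(diff(t(counts))) >= 0))  # lower angle cutoff
})

test_that("scatter tables separate the passing subset", {
  mkser <- function(v, kind) new("GeometrySeries", times = seq_along(v),
                                 values = v, kind = kind)
  rec <- nacFilter(mkser(c(3.0, 3.1), "distance"), mkser(c(170, 171), "angle"))
  expect_equal(nrow(nacScatter(rec, passingOnly = TRUE)), 2L)
  rec2 <- nacFilter(mkser(c(5, 6), "distance"), mkser(c(170, 171), "angle"))
  expect_equal(nrow(nacScatter(rec2, passingOnly = TRUE)), 0L)
  expect_equal(nrow(nacScatter(rec2)), 2L)
})

test_that("site definitions validate their atoms and the preset resolves them", {
  st <- siteToy()
  expect_error(siteDefinition(st$s, "bad", c(1L, 1L), c(O3 = 3L), 4L, 5L),
               "distinct")
  expect_error(siteDefinition(st$s, "bad", c(1L, 2L), c(O3 = 30L), 4L, 5L),
               "outside the structure")
  s <- makeToyDimer(smallSpec())
  site <- sitePreset(s, kChain = "A", lChain = "B", label = "L2-K1")
  expect_s4_class(site, "SiteDefinition")
  ad <- atomData(s)
  expect_equal(ad$name[site@gammaPhosphorus], "PG")
  expect_equal(ad$chain[site@gammaPhosphorus], "B")
  expect_equal(ad$name[site@closurePair], c("MG", "NE2"))
  # closure markers start exactly at the open-state separation
  d <- sqrt(sum((coords(s)[site@closurePair[1], ] -
                   coords(s)[site@closurePair[2], ])^2))
  expect_equal(d, 14, tolerance = 1e-9)
  apo <- makeToyDimer(smallSpec(), ligands = FALSE)
  expect_error(sitePreset(apo, kChain = "A", lChain = "B"), "not found")
})
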