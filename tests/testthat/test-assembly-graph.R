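# Pi-stacking detection geometry and assembly-graph classification.

hexagon <- function(centroid, normal, radius = 1.4, phase = 0) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- (0:5) * pi / 3 + phase
  t(vapply(ang, function(a) centroid + radius * (cos(a) * e1 + sin(a) * e2),
           numeric(3)))
}

stack_structure <- function(centroids, normals, ids = NULL) {
  ids <- ids %||% sprintf("M%02d", seq_along(centroids))
  coords <- NULL; rings <- list(); mol <- character(0)
  for (i in seq_along(centroids)) {
    xyz <- hexagon(centroids[[i]], normals[[i]])
    rings[[i]] <- ring_spec(ids[i], (if (is.null(coords)) 0 else nrow(coords)) + 1:6)
    coords <- rbind(coords, xyz)
    mol <- c(mol, rep(ids[i], 6))
  }
  structure3d(coords, data.frame(molecule_id = mol, group = "flavonoid_core"), rings)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("parallel, distant and perpendicular ring pairs are triaged correctly", {
  # coaxial parallel rings 3.5 A apart: one contact at the defaults
  s <- stack_structure(list(c(0, 0, 0), c(0, 0, 3.5)),
                       list(c(0, 0, 1), c(0, 0, 1)))
  ct <- detect_stacking_contacts(s)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$centroid_distance, 3.5, tolerance = 1e-9)
  expect_equal(ct$interplanar_angle, 0, tolerance = 1e-6)
  expect_equal(ct$lateral_offset, 0, tolerance = 1e-9)
  # 10 A apart: nothing
  far <- stack_structure(list(c(0, 0, 0), c(0, 0, 10)),
                         list(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(nrow(detect_stacking_contacts(far)), 0L)
  # perpendicular at 3.5 A: excluded under the parallel-only default,
  # admitted in T-shaped mode
  tsh <- stack_structure(list(c(0, 0, 0), c(0, 0, 3.5)),
                         list(c(0, 0, 1), c(1, 0, 0)))
  expect_equal(nrow(detect_stacking_contacts(tsh)), 0L)
  ct_t <- detect_stacking_contacts(tsh, t_shaped = TRUE)
  expect_equal(nrow(ct_t), 1L)
  expect_equal(ct_t$type, "t_shaped")
})

test_that("offset rule rejects slipped pairs beyond the threshold", {
  ok <- stack_structure(list(c(0, 0, 0), c(1.5, 0, 3.0)),
                        list(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(nrow(detect_stacking_contacts(ok)), 1L)
  slipped <- stack_structure(list(c(0, 0, 0), c(2.5, 0, 3.0)),
                             list(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(nrow(detect_stacking_contacts(slipped)), 0L)
})

test_that("detection is invariant under global rigid motion", {
  fb <- gen_ring_fiber(fiber_spec(6, branch_points = list(c(4, 1))))
  ct <- detect_stacking_contacts(fb)
  set.seed(2)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- fb
  moved$coords <- fb$coords %*% q + matrix(rep(c(12, -7, 3), each = nrow(fb$coords)),
                                           ncol = 3)
  ct2 <- detect_stacking_contacts(moved)
  expect_identical(ct2[, c("ring_i", "ring_j")], ct[, c("ring_i", "ring_j")])
  expect_equal(ct2$centroid_distance, ct$centroid_distance, tolerance = 1e-9)
  expect_equal(ct2$interplanar_angle, ct$interplanar_angle, tolerance = 1e-6)
})

test_that("contact detection validates its ring inputs", {
  s <- stack_structure(list(c(0, 0, 0)), list(c(0, 0, 1)))
  expect_error(ring_spec("M1", 1:4), class = "fa_validation_error")
  bad <- list(ring_spec("M1", 1:6), ring_spec("M2", 7:12))
  expect_error(detect_stacking_contacts(s$coords, bad), class = "fa_validation_error")
})

test_that("graph build collapses ring contacts to molecule edges and finds components", {
  # two disjoint stacks of 3 and 4, plus 2 singletons
  zs <- function(n, x0) lapply(seq_len(n), function(k) c(x0, 0, 3.5 * (k - 1)))
  s <- stack_structure(c(zs(3, 0), zs(4, 50)),
                       rep(list(c(0, 0, 1)), 7))
  ct <- detect_stacking_contacts(s)
  ag <- build_assembly_graph(ct, molecules = c(sprintf("M%02d", 1:7), "S1", "S2"))
  expect_equal(sort(ag$components$size), c(1, 1, 3, 4))
  expect_equal(sum(ag$components$class == "SINGLETON"), 2L)
  expect_true(all(ag$components$class[ag$components$size > 1] == "PRIMARY"))
  # no contacts at all: K singletons
  ag0 <- build_assembly_graph(ct[0, ], molecules = c("a", "b", "c"))
  expect_equal(ag0$components$class, rep("SINGLETON", 3))
  expect_error(build_assembly_graph(ct, molecules = "M01"),
               class = "fa_validation_error")
})

test_that("topology classes are exhaustive and mutually exclusive", {
  path5 <- igraph::make_graph(~ 1 - 2 - 3 - 4 - 5)
  expect_equal(classify_assembly(path5), "PRIMARY")
  tri <- igraph::make_full_graph(3)
  expect_equal(classify_assembly(tri), "CYCLIC")
  star <- igraph::make_star(4, "undirected")
  expect_equal(classify_assembly(star), "SECONDARY")
  expect_equal(classify_assembly(igraph::make_empty_graph(1, directed = FALSE)),
               "SINGLETON")
})

test_that("fiber specs are recovered exactly over a seeded sweep", {
  set.seed(77)
  for (i in 1:50) {
    n_units <- sample(2:9, 1)
    n_br <- sample(0:2, 1)
    bps <- list()
    if (n_br > 0) {
      units <- sample(seq_len(n_units), n_br)
      bps <- lapply(units, function(u) c(u, sample(1:3, 1)))
    }
    spec <- fiber_spec(n_units, branch_points = bps,
                       with_glycoside = runif(1) < 0.5)
    fb <- gen_ring_fiber(spec)
    truth <- attr(fb, "truth")
    ag <- build_assembly_graph(detect_stacking_contacts(fb),
                               molecules = unique(fb$atoms$molecule_id))
    expect_equal(nrow(ag$components), 1L)
    expect_equal(ag$components$size, truth$n_rings)
    expect_equal(ag$components$class, truth$class)
  }
})

test_that("linear fibers yield path graphs (order-independent build)", {
  fb <- gen_ring_fiber(fiber_spec(7))
  ct <- detect_stacking_contacts(fb)
  expect_equal(nrow(ct), 6L)   # consecutive rings only
  ag1 <- build_assembly_graph(ct, unique(fb$atoms$molecule_id))
  ag2 <- build_assembly_graph(ct[rev(seq_len(nrow(ct))), ],
                              unique(fb$atoms$molecule_id))
  expect_equal(ag1$components, ag2$components)
  expect_equal(ag1$components$class, "PRIMARY")
})
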