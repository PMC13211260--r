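test_that("complete fixture is a valid, bilaterally symmetric circle", {
  net <- make_cow_fixture("complete")
  expect_silent(validate_network(net))
  segs <- net$segments
  # the anatomical inventory of a complete circle
  for (nm in c("RICA", "LICA", "RVA", "LVA", "BA", "ACoA", "RPCoA",
               "LPCoA", "RPCAP1", "LPCAP1", "RPCAP2", "LPCAP2",
               "RMCA", "LMCA", "RACAA1", "LACAA1", "RACAA2", "LACAA2"))
    expect_true(nm %in% segs$id, label = paste("segment", nm))
  # at least two terminal outlet segments per territory
  terr <- outlet_territories(net)
  expect_true(all(table(terr) >= 2))
  # mirror symmetry: every sided segment has a homolog of equal geometry
  sided <- segs$id[substr(segs$id, 1, 1) %in% c("R", "L")]
  for (id in sided) {
    hom <- homolog_id(id)
    i <- which(segs$id == id); j <- which(segs$id == hom)
    expect_length(j, 1)
    expect_identical(segs$length[i], segs$length[j])
    expect_identical(segs$radius[i], segs$radius[j])
  }
  # boundary nodes all have degree one
  g <- cowflow:::network_graph(net)
  bnd <- net$nodes$id[net$nodes$role != "interior"]
  expect_true(all(igraph::degree(g)[bnd] == 1))
})

test_that("anatomical variants edit exactly one segment", {
  base <- make_cow_fixture("complete")
  fet <- make_cow_fixture("fetal_pcap1", side = "left")
  expect_false("LPCAP1" %in% fet$segments$id)
  expect_identical(nrow(fet$segments), nrow(base$segments) - 1L)
  expect_equal(igraph::components(cowflow:::network_graph(fet))$no, 1)
  merged <- merge(base$segments, fet$segments, by = "id")
  expect_true(all(merged$radius.x == merged$radius.y))

  hyp <- make_cow_fixture("hypoplastic_acaa1", side = "right")
  i <- which(hyp$segments$id == "RACAA1")
  expect_lt(2 * hyp$segments$radius[i], 0.8e-3)   # diameter below threshold
  expect_equal(2 * hyp$segments$radius[i], 0.5e-3)
  changed <- hyp$segments$radius != base$segments$radius
  expect_identical(sum(changed), 1L)
})

test_that("JSON round trip preserves every field bit-exactly", {
  net <- make_cow_fixture("complete")
  f <- withr::local_tempfile(fileext = ".json")
  save_network(net, f)
  back <- load_network(f)
  expect_identical(back$segments, net$segments)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$blood$viscosity, net$blood$viscosity)

  d <- withr::local_tempdir()
  save_network(net, d, format = "csv_pair")
  back2 <- load_network(d, format = "csv_pair")
  expect_equal(back2$segments, net$segments)
})

test_that("unit headers in network files are normalized to SI", {
  net <- make_cow_fixture("complete")
  f <- withr::local_tempfile(fileext = ".json")
  save_network(net, f)
  txt <- jsonlite::read_json(f, simplifyVector = TRUE)
  txt$units$length <- "mm"
  txt$segments$length <- txt$segments$length * 1000
  txt$segments$radius <- txt$segments$radius * 1000
  txt$segments$wall_thickness <- txt$segments$wall_thickness * 1000
  txt$segments$ref_area <- txt$segments$ref_area * 1e6
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(txt, f2, digits = NA, auto_unbox = TRUE, na = "null")
  back <- load_network(f2)
  expect_equal(back$segments$length, net$segments$length)
  expect_equal(back$segments$radius, net$segments$radius)
})

test_that("the shipped example network equals the generated fixture", {
  f <- system.file("extdata", "cow_complete_synthetic.json",
                   package = "cowflow")
  net <- load_network(f)
  expect_identical(net$segments, make_cow_fixture("complete")$segments)
})

test_that("schema and invariant violations are rejected with named records", {
  nodes <- data.frame(id = c("a", "b"),
                      role = c("inlet_source", "outlet_sink"),
                      territory = c(NA, "RMCA"))
  segs <- data.frame(id = "s", from = "a", to = "b", length = 0.01,
                     radius = 1e-3, wall_thickness = 3e-4,
                     youngs_modulus = 4e7)
  net <- vascular_network(nodes, segs)      # minimal valid network
  expect_identical(nrow(net$nodes), 2L)

  bad <- segs; bad$radius <- 0
  expect_error(vascular_network(nodes, bad), "nonpositive radius")
  bad <- segs; bad$to <- "a"
  expect_error(vascular_network(nodes, bad), "self loop")
  bad_nodes <- nodes; bad_nodes$territory <- c("RMCA", "RMCA")
  expect_error(vascular_network(bad_nodes, segs), "non-outlet")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(nodes = list()), f, auto_unbox = TRUE)
  expect_error(load_network(f), "schema violation")
})

test_that("stenosis geometry records Ds = D0 (1 - Rs) and rejects occlusion", {
  net <- make_cow_fixture("complete")
  expect_identical(apply_stenosis_geometry(net, "RPCAP1", 0), net)
  st <- apply_stenosis_geometry(net, "RPCAP1", 0.5)
  sp <- st$stenoses[["RPCAP1"]]
  expect_equal(sp$ds, 0.5 * sp$d0)
  expect_equal(sp$rs_percent, 50)
  expect_equal(sp$as, pi * sp$ds^2 / 4)
  # only the stenosis record differs; the segment table is untouched
  expect_identical(st$segments, net$segments)
  expect_error(apply_stenosis_geometry(net, "RPCAP1", 1), "occlusion")
  expect_error(apply_stenosis_geometry(net, "nope", 0.5), "unknown segment")
})
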