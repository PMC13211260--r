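# Graph data model for the arterial network: construction, validation,
# JSON/CSV I/O, the canonical synthetic Circle-of-Willis fixture and
# anatomical-variant editing.

NODE_ROLES <- c("inlet_source", "interior", "outlet_sink")
TERRITORIES <- c("RACA", "LACA", "RMCA", "LMCA", "RPCA", "LPCA")

#' Blood rheological properties
#'
#' @param viscosity dynamic viscosity in Pa s.
#' @param density density in kg/m^3.
#' @return a `blood_properties` list.
#' @export
blood_properties <- function(viscosity = 0.0045, density = 1050) {
  stopifnot(is.numeric(viscosity), viscosity > 0,
            is.numeric(density), density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "blood_properties")
}

#' Construct a vascular network
#'
#' A `vascular_network` holds a node table, a segment table and blood
#' properties.  Segments are stored undirected with a declared reference
#' orientation `from -> to`; all signed flows in the package are relative
#' to that orientation.
#'
#' @param nodes data.frame with columns `id`, `role` (one of
#'   `inlet_source`, `interior`, `outlet_sink`), `territory` (one of the
#'   six territory labels for outlet sinks, `NA` otherwise) and optional
#'   coordinates `x`, `y`, `z` in metres.
#' @param segments data.frame with columns `id`, `from`, `to`, `length`,
#'   `radius`, `wall_thickness`, `youngs_modulus` (SI units), optional
#'   `ref_area` (defaults to `pi * radius^2`) and optional anatomical
#'   `name` (defaults to `id`).
#' @param blood a [blood_properties()] object.
#' @param validate check network invariants (connectivity, degree-one
#'   inlets and outlets, positive geometry).
#' @return a validated `vascular_network` object.
#' @export
vascular_network <- function(nodes, segments, blood = blood_properties(),
                             validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (is.null(nodes$territory)) nodes$territory <- NA_character_
  for (cc in c("x", "y", "z")) if (is.null(nodes[[cc]])) nodes[[cc]] <- NA_real_
  if (is.null(segments$ref_area)) segments$ref_area <- pi * segments$radius^2
  if (is.null(segments$name)) segments$name <- segments$id
  # storage mode must be double for bit-exact file round trips
  for (cc in c("length", "radius", "wall_thickness", "youngs_modulus",
               "ref_area"))
    segments[[cc]] <- as.numeric(segments[[cc]])
  for (cc in c("x", "y", "z")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  nodes <- nodes[c("id", "role", "territory", "x", "y", "z")]
  segments <- segments[c("id", "from", "to", "length", "radius",
                         "wall_thickness", "youngs_modulus", "ref_area",
                         "name")]
  rownames(nodes) <- NULL
  rownames(segments) <- NULL
  net <- structure(list(nodes = nodes, segments = segments, blood = blood,
                        stenoses = list()),
                   class = "vascular_network")
  if (validate) validate_network(net)
  net
}

#' Validate a vascular network against its structural invariants
#'
#' Checks id uniqueness, role/territory consistency, positive geometry,
#' reference-area consistency (`A0 = pi r^2` to 1e-12 relative),
#' connectivity, and that every inlet source and outlet sink has graph
#' degree one.
#'
#' @param net a `vascular_network`.
#' @return `net`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  segs <- net$segments
  if (anyDuplicated(nodes$id))
    stop("validation error: duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (anyDuplicated(segs$id))
    stop("validation error: duplicate segment ids: ",
         paste(unique(segs$id[duplicated(segs$id)]), collapse = ", "))
  bad_role <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad_role))
    stop("validation error: unknown node role: ", paste(bad_role, collapse = ", "))
  is_out <- nodes$role == "outlet_sink"
  if (any(is_out & is.na(nodes$territory)))
    stop("validation error: outlet sink without territory: ",
         paste(nodes$id[is_out & is.na(nodes$territory)], collapse = ", "))
  if (any(!is_out & !is.na(nodes$territory)))
    stop("validation error: territory set on non-outlet node: ",
         paste(nodes$id[!is_out & !is.na(nodes$territory)], collapse = ", "))
  bad_terr <- setdiff(nodes$territory[is_out], TERRITORIES)
  if (length(bad_terr))
    stop("validation error: unknown territory: ", paste(bad_terr, collapse = ", "))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (!(s$from %in% nodes$id) || !(s$to %in% nodes$id))
      stop("validation error: segment ", s$id, " references unknown node")
    if (s$from == s$to)
      stop("validation error: segment ", s$id, " is a self loop")
    if (!is.finite(s$length) || s$length <= 0)
      stop("validation error: segment ", s$id, " has nonpositive length")
    if (!is.finite(s$radius) || s$radius <= 0)
      stop("validation error: segment ", s$id, " has nonpositive radius")
    a0 <- pi * s$radius^2
    if (abs(s$ref_area - a0) > 1e-12 * a0)
      stop("validation error: segment ", s$id,
           " reference area inconsistent with pi*r^2")
  }
  if (sum(nodes$role == "inlet_source") < 1 || sum(is_out) < 1)
    stop("validation error: need at least one inlet source and one outlet sink")
  g <- network_graph(net)
  if (igraph::components(g)$no != 1)
    stop("topology error: network graph is disconnected")
  deg <- igraph::degree(g)
  bnd <- nodes$id[nodes$role != "interior"]
  bad <- bnd[deg[bnd] != 1]
  if (length(bad))
    stop("validation error: boundary node(s) with degree != 1: ",
         paste(bad, collapse = ", "))
  invisible(net)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$segments), " segments\n", sep = "")
  cat("  inlets:  ",
      paste(x$nodes$id[x$nodes$role == "inlet_source"], collapse = ", "), "\n")
  cat("  outlets: ", sum(x$nodes$role == "outlet_sink"),
      " across territories ",
      paste(sort(unique(stats::na.omit(x$nodes$territory))), collapse = ", "),
      "\n", sep = "")
  if (length(x$stenoses))
    cat("  stenoses:", paste(vapply(x$stenoses, function(s)
      sprintf("%s (%.0f%%)", s$segment_id, s$rs_percent), ""), collapse = ", "),
      "\n")
  invisible(x)
}

# undirected igraph view with segment ids on the edges
network_graph <- function(net) {
  igraph::graph_from_data_frame(
    net$segments[c("from", "to", "id")],
    directed = FALSE,
    vertices = net$nodes["id"])
}

#' Write a vascular network to disk
#'
#' JSON files carry a `units` header (always `"m"` internally written),
#' the blood properties, and the node/segment tables; `csv_pair` writes
#' `nodes.csv` and `segments.csv` into a directory.
#'
#' @param net a `vascular_network`.
#' @param path target file (json) or directory (csv_pair).
#' @param format `"json"` or `"csv_pair"`.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, format = c("json", "csv_pair")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      units = list(length = "m", pressure = "Pa"),
      blood = list(viscosity = net$blood$viscosity,
                   density = net$blood$density),
      nodes = net$nodes,
      segments = net$segments)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                         dataframe = "rows", na = "null", pretty = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    write.csv(net$nodes, file.path(path, "nodes.csv"), row.names = FALSE)
    write.csv(net$segments, file.path(path, "segments.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Load a vascular network from disk
#'
#' Inverse of [save_network()].  JSON files may declare `units$length`
#' as `"m"`, `"mm"` or `"cm"`; geometric fields (length, radius,
#' wall thickness, coordinates) are converted to metres and `ref_area`
#' is rescaled accordingly.
#'
#' @param path JSON file or directory holding `nodes.csv`/`segments.csv`.
#' @param format `"json"` or `"csv_pair"`.
#' @return a validated `vascular_network`.
#' @export
load_network <- function(path, format = c("json", "csv_pair")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) stop("file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (fld in c("nodes", "segments"))
      if (is.null(obj[[fld]])) stop("schema violation: missing '", fld, "' field")
    scale <- switch(if (is.null(obj$units$length)) "m" else obj$units$length,
                    m = 1, mm = 1e-3, cm = 1e-2,
                    stop("schema violation: unknown length unit '",
                         obj$units$length, "'"))
    nodes <- as.data.frame(obj$nodes)
    segs <- as.data.frame(obj$segments)
    req_n <- c("id", "role")
    req_s <- c("id", "from", "to", "length", "radius", "wall_thickness",
               "youngs_modulus")
    miss <- setdiff(req_n, names(nodes))
    if (length(miss)) stop("schema violation: nodes missing column(s): ",
                           paste(miss, collapse = ", "))
    miss <- setdiff(req_s, names(segs))
    if (length(miss)) stop("schema violation: segments missing column(s): ",
                           paste(miss, collapse = ", "))
    if (scale != 1) {
      for (cc in c("x", "y", "z"))
        if (!is.null(nodes[[cc]])) nodes[[cc]] <- nodes[[cc]] * scale
      for (cc in c("length", "radius", "wall_thickness"))
        segs[[cc]] <- segs[[cc]] * scale
      if (!is.null(segs$ref_area)) segs$ref_area <- segs$ref_area * scale^2
    }
    blood <- if (is.null(obj$blood)) blood_properties() else
      blood_properties(obj$blood$viscosity, obj$blood$density)
    vascular_network(nodes, segs, blood)
  } else {
    nf <- file.path(path, "nodes.csv")
    sf <- file.path(path, "segments.csv")
    if (!file.exists(nf) || !file.exists(sf))
      stop("file not found: expected ", nf, " and ", sf)
    vascular_network(read.csv(nf), read.csv(sf))
  }
}

# -------------------------------------------------------------------------
# Canonical Circle-of-Willis fixture

# One-sided geometry table (lengths/radii in metres); midline segments are
# listed once.  Values are literature-plausible calibre and length choices
# for an adult CoW; they are configuration, not measurement.
cow_geometry <- function() {
  sided <- data.frame(
    stem = c("ICA", "VA", "PCAP1", "PCAP2", "PCoA", "MCA", "ACAA1",
             "ACAA2", "MCA_T1", "MCA_T2", "ACA_T1", "ACA_T2",
             "PCA_T1", "PCA_T2"),
    length = c(0.120, 0.100, 0.008, 0.040, 0.015, 0.030, 0.014,
               0.025, 0.020, 0.020, 0.020, 0.020, 0.020, 0.020),
    radius = c(2.0e-3, 1.5e-3, 1.1e-3, 1.05e-3, 0.7e-3, 1.4e-3, 1.1e-3,
               1.1e-3, 0.7e-3, 0.7e-3, 0.6e-3, 0.6e-3, 0.6e-3, 0.6e-3),
    stringsAsFactors = FALSE)
  midline <- data.frame(
    stem = c("BA", "ACoA"),
    length = c(0.025, 0.003),
    radius = c(1.6e-3, 0.7e-3),
    stringsAsFactors = FALSE)
  list(sided = sided, midline = midline,
       wall_thickness = 0.3e-3, youngs_modulus = 4e7)
}

#' Synthetic Circle-of-Willis network fixture
#'
#' Builds a bilaterally symmetric cerebral arterial network: two internal
#' carotid arteries (ICA) and two vertebral arteries (VA) as inflow
#' sources, the VAs merging into the basilar artery (BA), paired
#' ACA-A1/A2, MCA and PCA-P1/P2 segments, the anterior communicating
#' artery (ACoA), paired posterior communicating arteries (PCoA), and two
#' terminal outlet segments per territory (RACA, LACA, RMCA, LMCA, RPCA,
#' LPCA).  Geometry is a documented set of literature-plausible radii
#' (0.6-2 mm) and lengths (3-120 mm).
#'
#' Variants edit exactly one segment relative to the complete network:
#' `fetal_pcap1` removes the chosen side's PCA-P1 so the PCA-P2 is fed
#' from the ipsilateral ICA through the PCoA; `hypoplastic_acaa1` sets
#' the chosen side's ACA-A1 diameter to `hypoplastic_diameter` (default
#' 0.5 mm, below the 0.8 mm hypoplasia threshold).
#'
#' @param variant `"complete"`, `"fetal_pcap1"` or `"hypoplastic_acaa1"`.
#' @param side `"left"` or `"right"`; the side carrying the variant.
#' @param seed integer seed used only when `jitter > 0`.
#' @param jitter optional fractional log-normal jitter applied to lengths
#'   and radii (breaks the mirror symmetry; default 0, i.e. exactly
#'   symmetric).
#' @param hypoplastic_diameter diameter assigned to a hypoplastic ACA-A1,
#'   in metres.
#' @return a validated `vascular_network`.
#' @export
make_cow_fixture <- function(variant = c("complete", "fetal_pcap1",
                                         "hypoplastic_acaa1"),
                             side = c("left", "right"), seed = 0L,
                             jitter = 0, hypoplastic_diameter = 0.5e-3) {
  variant <- match.arg(variant)
  side <- match.arg(side)
  pre <- if (side == "left") "L" else "R"
  geo <- cow_geometry()

  node <- function(id, role = "interior", territory = NA_character_,
                   x = NA_real_, y = NA_real_, z = NA_real_)
    data.frame(id = id, role = role, territory = territory,
               x = x, y = y, z = z, stringsAsFactors = FALSE)

  sgn <- c(R = 1, L = -1)
  nodes <- do.call(rbind, c(
    list(node("VB", x = 0, y = -0.030, z = -0.010),
         node("BA_top", x = 0, y = -0.025, z = 0.010)),
    lapply(c("R", "L"), function(p) rbind(
      node(paste0(p, "ICA_in"), "inlet_source", x = sgn[p] * 0.015,
           y = 0.010, z = -0.110),
      node(paste0(p, "VA_in"), "inlet_source", x = sgn[p] * 0.008,
           y = -0.030, z = -0.100),
      node(paste0(p, "ICA_top"), x = sgn[p] * 0.015, y = 0.005, z = 0.010),
      node(paste0(p, "PCA_jx"), x = sgn[p] * 0.008, y = -0.020, z = 0.012),
      node(paste0(p, "ACoA_jx"), x = sgn[p] * 0.002, y = 0.018, z = 0.012),
      node(paste0(p, "MCA_br"), x = sgn[p] * 0.045, y = 0.005, z = 0.015),
      node(paste0(p, "ACA_br"), x = sgn[p] * 0.004, y = 0.040, z = 0.020),
      node(paste0(p, "PCA_br"), x = sgn[p] * 0.030, y = -0.050, z = 0.020),
      node(paste0(p, "MCA_t1"), "outlet_sink", paste0(p, "MCA"),
           x = sgn[p] * 0.060, y = 0.010, z = 0.020),
      node(paste0(p, "MCA_t2"), "outlet_sink", paste0(p, "MCA"),
           x = sgn[p] * 0.060, y = -0.005, z = 0.025),
      node(paste0(p, "ACA_t1"), "outlet_sink", paste0(p, "ACA"),
           x = sgn[p] * 0.006, y = 0.055, z = 0.030),
      node(paste0(p, "ACA_t2"), "outlet_sink", paste0(p, "ACA"),
           x = sgn[p] * 0.010, y = 0.050, z = 0.040),
      node(paste0(p, "PCA_t1"), "outlet_sink", paste0(p, "PCA"),
           x = sgn[p] * 0.040, y = -0.065, z = 0.025),
      node(paste0(p, "PCA_t2"), "outlet_sink", paste0(p, "PCA"),
           x = sgn[p] * 0.035, y = -0.070, z = 0.015)))))

  gs <- geo$sided
  row_of <- function(stem) gs[gs$stem == stem, ]
  seg <- function(id, from, to, stem_row)
    data.frame(id = id, from = from, to = to, length = stem_row$length,
               radius = stem_row$radius, wall_thickness = geo$wall_thickness,
               youngs_modulus = geo$youngs_modulus,
               ref_area = pi * stem_row$radius^2, name = id,
               stringsAsFactors = FALSE)

  side_segs <- function(p) rbind(
    seg(paste0(p, "ICA"), paste0(p, "ICA_in"), paste0(p, "ICA_top"),
        row_of("ICA")),
    seg(paste0(p, "VA"), paste0(p, "VA_in"), "VB", row_of("VA")),
    seg(paste0(p, "PCAP1"), "BA_top", paste0(p, "PCA_jx"), row_of("PCAP1")),
    seg(paste0(p, "PCAP2"), paste0(p, "PCA_jx"), paste0(p, "PCA_br"),
        row_of("PCAP2")),
    seg(paste0(p, "PCoA"), paste0(p, "ICA_top"), paste0(p, "PCA_jx"),
        row_of("PCoA")),
    seg(paste0(p, "MCA"), paste0(p, "ICA_top"), paste0(p, "MCA_br"),
        row_of("MCA")),
    seg(paste0(p, "ACAA1"), paste0(p, "ICA_top"), paste0(p, "ACoA_jx"),
        row_of("ACAA1")),
    seg(paste0(p, "ACAA2"), paste0(p, "ACoA_jx"), paste0(p, "ACA_br"),
        row_of("ACAA2")),
    seg(paste0(p, "MCA_T1"), paste0(p, "MCA_br"), paste0(p, "MCA_t1"),
        row_of("MCA_T1")),
    seg(paste0(p, "MCA_T2"), paste0(p, "MCA_br"), paste0(p, "MCA_t2"),
        row_of("MCA_T2")),
    seg(paste0(p, "ACA_T1"), paste0(p, "ACA_br"), paste0(p, "ACA_t1"),
        row_of("ACA_T1")),
    seg(paste0(p, "ACA_T2"), paste0(p, "ACA_br"), paste0(p, "ACA_t2"),
        row_of("ACA_T2")),
    seg(paste0(p, "PCA_T1"), paste0(p, "PCA_br"), paste0(p, "PCA_t1"),
        row_of("PCA_T1")),
    seg(paste0(p, "PCA_T2"), paste0(p, "PCA_br"), paste0(p, "PCA_t2"),
        row_of("PCA_T2")))

  gm <- geo$midline
  segs <- rbind(
    side_segs("R"), side_segs("L"),
    seg("BA", "VB", "BA_top", gm[gm$stem == "BA", ]),
    # reference orientation right -> left across the midline
    seg("ACoA", "RACoA_jx", "LACoA_jx", gm[gm$stem == "ACoA", ]))

  if (jitter > 0) {
    set.seed(as.integer(seed))
    segs$length <- segs$length * exp(stats::rnorm(nrow(segs), 0, jitter))
    segs$radius <- segs$radius * exp(stats::rnorm(nrow(segs), 0, jitter))
    segs$ref_area <- pi * segs$radius^2
  }

  if (variant == "fetal_pcap1") {
    segs <- segs[segs$id != paste0(pre, "PCAP1"), ]
  } else if (variant == "hypoplastic_acaa1") {
    i <- which(segs$id == paste0(pre, "ACAA1"))
    segs$radius[i] <- hypoplastic_diameter / 2
    segs$ref_area[i] <- pi * segs$radius[i]^2
  }

  vascular_network(nodes, segs)
}

#' Map a segment id to its contralateral homolog
#'
#' `"RMCA"` maps to `"LMCA"` and vice versa; midline segments (BA, ACoA)
#' map to themselves.
#'
#' @param ids character vector of segment ids.
#' @return character vector of homolog ids.
#' @export
homolog_id <- function(ids) {
  vapply(ids, function(id) {
    if (id %in% c("BA", "ACoA", "VB")) return(id)
    p <- substr(id, 1, 1)
    if (p == "R") paste0("L", substring(id, 2))
    else if (p == "L") paste0("R", substring(id, 2))
    else id
  }, "")
}

#' Record a localized stenosis on a segment
#'
#' Stores the geometric stenosis description on the network: the stenotic
#' diameter is `Ds = D0 * (1 - rs)` where `rs` is the fractional diameter
#' reduction; the healthy diameter `D0` is retained for the flow-dependent
#' pressure-drop model.  The 1D solver reduces the reference
#' cross-sectional area to `pi Ds^2 / 4` over a centred span of length
#' `ls` (default 20% of the segment length) with two-cell smoothed
#' shoulders.
#'
#' @param net a `vascular_network`.
#' @param segment_id id of the affected segment.
#' @param rs fractional diameter reduction in `[0, 1)`; `rs = 0` returns
#'   the network unchanged, `rs >= 1` (occlusion) is an error — model
#'   occlusions as a variant/removal instead.
#' @param ls stenosis length in metres, default `0.2 * length`.
#' @return a modified copy of `net`.
#' @export
apply_stenosis_geometry <- function(net, segment_id, rs, ls = NULL) {
  i <- which(net$segments$id == segment_id)
  if (!length(i)) stop("unknown segment id: ", segment_id)
  if (!is.numeric(rs) || rs < 0 || rs >= 1)
    stop("stenosis degree rs must lie in [0, 1); complete occlusion ",
         "(rs = 1) must be modeled as a variant/removal")
  if (rs == 0) return(net)
  s <- net$segments[i, ]
  if (is.null(ls)) ls <- 0.2 * s$length
  if (ls <= 0 || ls > s$length) stop("stenosis length outside segment")
  d0 <- 2 * s$radius
  spec <- stenosis_spec(segment_id = segment_id, d0 = d0,
                        ds = d0 * (1 - rs), ls = ls)
  net$stenoses[[segment_id]] <- spec
  net
}

#' @export
as.data.frame.vascular_network <- function(x, ...) x$segments
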