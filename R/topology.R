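#' Build a converging bifurcating lymphatic network
#'
#' Constructs the symmetric tree of vessels used throughout the package:
#' generation `G = n_generations` holds the `2^(G-1)` inlet vessels, each pair
#' of sibling vessels converges at a junction into a parent vessel, and
#' generation 1 is the single outlet vessel. Every vessel holds `nv`
#' lymphangions in series. Valves sit between adjacent lymphangions within a
#' vessel, at every vessel outlet (the two children's terminal valves serve as
#' the parent's inlet valves at each junction), and at each inlet-generation
#' entrance.
#'
#' Lymphangions are ordered canonically: inlet generation first, left to
#' right, then generation by generation toward the outlet; within a vessel,
#' upstream to downstream.
#'
#' @param n_generations Number of vessel generations (default 3, the
#'   seven-vessel tree).
#' @param nv Number of lymphangions per vessel.
#' @return An object of class `lymph_topology`: a list with tibbles `vessels`,
#'   `lymphangions`, `segments`, `junctions` plus the scalars
#'   `n_generations` and `nv`.
#' @examples
#' topo <- build_network(3, 4)
#' nrow(topo$lymphangions)  # 28
#' @export
build_network <- function(n_generations = 3, nv = 4) {
  if (n_generations < 1 || nv < 1 ||
      n_generations != round(n_generations) || nv != round(nv)) {
    stop("n_generations and nv must be positive integers", call. = FALSE)
  }
  G <- as.integer(n_generations)
  nv <- as.integer(nv)

  gens <- rev(seq_len(G))  # inlet generation first
  vessels <- purrr::map_dfr(gens, function(g) {
    tibble::tibble(generation = g, index = seq_len(2^(g - 1)))
  })
  vessels <- dplyr::mutate(
    vessels,
    vessel_id = dplyr::row_number(),
    label = sprintf("%02d%02d", .data$generation, .data$index)
  )
  key <- function(g, k) {
    vessels$vessel_id[vessels$generation == g][k]
  }
  vessels$parent <- purrr::map2_int(
    vessels$generation, vessels$index,
    function(g, k) if (g > 1) key(g - 1L, ceiling(k / 2)) else NA_integer_
  )
  vessels$child1 <- purrr::map2_int(
    vessels$generation, vessels$index,
    function(g, k) if (g < G) key(g + 1L, 2L * k - 1L) else NA_integer_
  )
  vessels$child2 <- purrr::map2_int(
    vessels$generation, vessels$index,
    function(g, k) if (g < G) key(g + 1L, 2L * k) else NA_integer_
  )
  vessels <- vessels[, c("vessel_id", "generation", "index", "label",
                         "parent", "child1", "child2")]

  lymphangions <- tidyr::crossing(
    vessel_id = vessels$vessel_id, position = seq_len(nv)
  )
  lymphangions <- dplyr::arrange(lymphangions, .data$vessel_id,
                                 .data$position)
  lymphangions <- dplyr::mutate(
    lymphangions,
    lymph_id = dplyr::row_number(),
    generation = vessels$generation[.data$vessel_id],
    label = paste0(vessels$label[.data$vessel_id], "-",
                   sprintf("%02d", .data$position))
  )
  lymphangions <- lymphangions[, c("lymph_id", "vessel_id", "generation",
                                   "position", "label")]

  lid <- function(v, pos) {
    lymphangions$lymph_id[lymphangions$vessel_id == v &
                            lymphangions$position == pos]
  }

  # Segments, canonical order: per vessel (inlet generation first), the
  # vessel's inflow segment, its internal segments, then its terminal segment.
  seg <- list()
  junc <- list()
  add_seg <- function(up_type, up_id, down_type, down_id, has_valve, role,
                      vessel_id) {
    seg[[length(seg) + 1L]] <<- tibble::tibble(
      up_type = up_type, up_id = up_id, down_type = down_type,
      down_id = down_id, has_valve = has_valve, role = role,
      vessel_id = vessel_id
    )
    length(seg)
  }
  # junction ids follow parent vessels in canonical vessel order
  parent_vessels <- vessels$vessel_id[vessels$generation < G]
  junction_of_parent <- setNames(seq_along(parent_vessels),
                                 as.character(parent_vessels))

  inflow_seg <- integer(nrow(vessels))
  terminal_seg <- integer(nrow(vessels))
  for (v in vessels$vessel_id) {
    g <- vessels$generation[v]
    if (g == G) {
      inflow_seg[v] <- add_seg("inlet", 0L, "lymph", lid(v, 1L), TRUE,
                               "inlet", v)
    } else {
      j <- junction_of_parent[[as.character(v)]]
      inflow_seg[v] <- add_seg("junction", j, "lymph", lid(v, 1L), FALSE,
                               "junction_parent", v)
    }
    if (nv > 1) {
      for (pos in seq_len(nv - 1L)) {
        add_seg("lymph", lid(v, pos), "lymph", lid(v, pos + 1L), TRUE,
                "intra", v)
      }
    }
    if (g == 1) {
      terminal_seg[v] <- add_seg("lymph", lid(v, nv), "outlet", 0L, TRUE,
                                 "outlet", v)
    } else {
      j <- junction_of_parent[[as.character(vessels$parent[v])]]
      terminal_seg[v] <- add_seg("lymph", lid(v, nv), "junction", j, TRUE,
                                 "terminal", v)
    }
  }
  segments <- dplyr::bind_rows(seg)
  segments <- dplyr::mutate(segments, seg_id = dplyr::row_number(),
                            .before = 1)

  empty_junctions <- tibble::tibble(
    junction_id = integer(), parent_vessel = integer(),
    child1_vessel = integer(), child2_vessel = integer(),
    child_seg1 = integer(), child_seg2 = integer(), parent_seg = integer()
  )
  junctions <- purrr::map_dfr(parent_vessels, function(v) {
    tibble::tibble(
      junction_id = junction_of_parent[[as.character(v)]],
      parent_vessel = v,
      child1_vessel = vessels$child1[v],
      child2_vessel = vessels$child2[v],
      child_seg1 = terminal_seg[vessels$child1[v]],
      child_seg2 = terminal_seg[vessels$child2[v]],
      parent_seg = inflow_seg[v]
    )
  })
  if (!nrow(junctions)) junctions <- empty_junctions

  # per-lymphangion inflow/outflow segments
  lymphangions$in_seg <- purrr::map2_int(
    lymphangions$vessel_id, lymphangions$position,
    function(v, pos) {
      if (pos == 1L) as.integer(inflow_seg[v])
      else segments$seg_id[segments$role == "intra" &
                             segments$down_id == lid(v, pos)]
    }
  )
  lymphangions$out_seg <- purrr::map2_int(
    lymphangions$vessel_id, lymphangions$position,
    function(v, pos) {
      if (pos == nv) as.integer(terminal_seg[v])
      else segments$seg_id[segments$role == "intra" &
                             segments$up_id == lid(v, pos)]
    }
  )

  structure(
    list(n_generations = G, nv = nv, vessels = vessels,
         lymphangions = lymphangions, segments = segments,
         junctions = junctions,
         outlet_seg = terminal_seg[vessels$vessel_id[vessels$generation == 1]],
         inlet_segs = inflow_seg[vessels$vessel_id[vessels$generation == G]]),
    class = "lymph_topology"
  )
}

#' @export
print.lymph_topology <- function(x, ...) {
  cat(sprintf(
    "<lymph_topology> %d generations, %d vessels, %d lymphangions (nv = %d), %d junctions, %d valves\n",
    x$n_generations, nrow(x$vessels), nrow(x$lymphangions), x$nv,
    nrow(x$junctions), sum(x$segments$has_valve)))
  invisible(x)
}

#' Per-lymphangion contraction start times
#'
#' Assigns each lymphangion the start time of its contraction within the
#' global cycle `T = Tc + tr`. The wave starts at the inlet generation and
#' propagates toward the outlet: a lymphangion at position `j` in a vessel of
#' generation `g` starts at `(G - g) * ((nv - 1)*dtv + dtg) + (j - 1)*dtv`,
#' reduced modulo `T`, where `G` is the inlet generation. `dtv` is the delay
#' between adjacent lymphangions within a vessel; `dtg` is the extra delay
#' incurred at each junction crossing.
#'
#' @param topology A [build_network()] object.
#' @param dtv Intra-vessel delay, s (>= 0).
#' @param dtg Junction delay, s (>= 0).
#' @param Tc Contraction period `1/f`, s.
#' @param tr Diastolic period, s.
#' @return An object of class `lymph_schedule`: a tibble with one row per
#'   lymphangion and its start `offset` in seconds, carrying `dtv`, `dtg` and
#'   the cycle `T` as attributes.
#' @examples
#' topo <- build_network(3, 4)
#' contraction_schedule(topo, dtv = 0.5, dtg = 0.5, Tc = 2, tr = 1.5)
#' @export
contraction_schedule <- function(topology, dtv = 0.5, dtg = 0.5, Tc = 2,
                                 tr = 1.5) {
  stopifnot(inherits(topology, "lymph_topology"))
  if (dtv < 0 || dtg < 0) stop("delays must be nonnegative", call. = FALSE)
  T <- Tc + tr
  G <- topology$n_generations
  nv <- topology$nv
  sched <- dplyr::mutate(
    topology$lymphangions,
    offset = ((G - .data$generation) * ((nv - 1) * dtv + dtg) +
                (.data$position - 1) * dtv) %% T
  )
  sched <- sched[, c("lymph_id", "vessel_id", "generation", "position",
                     "label", "offset")]
  structure(tibble::as_tibble(sched),
            dtv = dtv, dtg = dtg, Tc = Tc, tr = tr, T = T,
            class = c("lymph_schedule", class(tibble::tibble())))
}

#' Equivalent delay of a reverse-propagating contraction wave
#'
#' A joint delay `dt` applied in the forward (inlet-to-outlet) direction is
#' equivalent, by periodicity, to a wave travelling in the reverse direction
#' with delay `T - dt`, where `T = Tc + tr` is the full cycle. Delays below
#' `T/2` are classified as forward-propagating waves; larger delays as
#' reverse.
#'
#' @param dt Joint delay(s), s, in `[0, T]`.
#' @param Tc Contraction period, s.
#' @param tr Diastolic period, s.
#' @return The equivalent reverse-direction delay(s), s.
#' @seealso [delay_direction()]
#' @export
reverse_equivalent_delay <- function(dt, Tc = 2, tr = 1.5) {
  T <- Tc + tr
  if (any(dt < 0 | dt > T)) stop("dt must lie in [0, T]", call. = FALSE)
  T - dt
}

#' @rdname reverse_equivalent_delay
#' @return `delay_direction()` returns `"forward"` or `"reverse"` per delay.
#' @export
delay_direction <- function(dt, Tc = 2, tr = 1.5) {
  T <- Tc + tr
  ifelse(dt < T / 2, "forward", "reverse")
}

#' Boundary pressures of the network
#'
#' Inlet pressure `pa` (applied at every inlet-generation entrance), outlet
#' pressure `pb`, and the uniform steady external pressure `pe`. Values are
#' given in cmH2O (the reporting unit) and stored internally in dyn/cm2.
#'
#' @param pa,pb,pe Pressures in cmH2O.
#' @return An object of class `lymph_bc` with fields `pa`, `pb`, `pe`
#'   (dyn/cm2), their cmH2O counterparts, and the axial difference
#'   `dP = pb - pa` (cmH2O).
#' @examples
#' boundary_conditions(pa = 6, pb = 9, pe = 2)
#' @export
boundary_conditions <- function(pa = 6, pb = 9, pe = 2) {
  structure(
    list(pa = cmh2o_to_dyncm2(pa), pb = cmh2o_to_dyncm2(pb),
         pe = cmh2o_to_dyncm2(pe),
         pa_cmH2O = pa, pb_cmH2O = pb, pe_cmH2O = pe,
         dP_cmH2O = pb - pa),
    class = "lymph_bc"
  )
}

#' @export
print.lymph_bc <- function(x, ...) {
  cat(sprintf(
    "<lymph_bc> pa = %g, pb = %g, pe = %g cmH2O (dP = %g cmH2O)\n",
    x$pa_cmH2O, x$pb_cmH2O, x$pe_cmH2O, x$dP_cmH2O))
  invisible(x)
}
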