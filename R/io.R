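#' Export the cell network
#'
#' Writes the osteoblast/osteocyte communication network of a simulation
#' state. For `format = "edge-csv"` two CSV files are produced: the edge
#' list at `path` with columns `src_id,dst_id,t_created,src_type,dst_type`
#' (multi-edges preserved, one row each) and a node table at
#' `*_nodes.csv` with columns `id,type,x_mm,y_mm,t_buried` (surface
#' osteoblasts have `x_mm` at the current front and empty `t_buried`).
#' For `format = "graphml"` a GraphML file is written via igraph with
#' multi-edges collapsed and their count stored in an edge attribute
#' `multiplicity`. Coordinates are persisted with 9 significant digits.
#'
#' @param state An `abm_state`.
#' @param path Output file path.
#' @param format `"edge-csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(state, path, format = c("edge-csv", "graphml")) {
  format <- match.arg(format)
  ob <- state$ob
  ot <- state$ot
  surf_x <- if (length(ob$id)) surface_x_at(state$surface, ob$y) else numeric(0)
  nodes <- data.frame(
    id = c(ob$id, ot$id),
    type = c(rep("osteoblast", length(ob$id)), rep("osteocyte", length(ot$id))),
    x_mm = signif(c(surf_x, ot$x), 9),
    y_mm = signif(c(ob$y, ot$y), 9),
    t_buried = c(rep(NA_real_, length(ob$id)), ot$buried_t),
    stringsAsFactors = FALSE
  )
  type_of <- stats::setNames(nodes$type, nodes$id)
  edges <- data.frame(
    src_id = state$edges$src, dst_id = state$edges$dst,
    t_created = state$edges$t,
    src_type = unname(type_of[as.character(state$edges$src)]),
    dst_type = unname(type_of[as.character(state$edges$dst)]),
    stringsAsFactors = FALSE
  )
  if (format == "edge-csv") {
    utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
    utils::write.csv(nodes, sub("(\\.csv)?$", "_nodes.csv", path, perl = TRUE)[1],
                     row.names = FALSE, quote = FALSE, na = "")
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) data.frame(from = as.character(edges$src_id),
                                to = as.character(edges$dst_id))
    else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id), type = nodes$type,
                          x_mm = nodes$x_mm, y_mm = nodes$y_mm,
                          t_buried = ifelse(is.na(nodes$t_buried), -1,
                                            nodes$t_buried)))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  mult <- igraph::count_multiple(g)
  key <- function(gr) {
    e <- igraph::as_edgelist(gr)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  igraph::E(gs)$multiplicity <- mult[match(key(gs), key(g))]
  igraph::write_graph(gs, path, format = "graphml")
  invisible(path)
}

#' Read an exported edge list back
#'
#' Round-trips the `edge-csv` format written by [export_network()].
#'
#' @param path Path to the edge CSV.
#' @return Data.frame with columns `src_id`, `dst_id`, `t_created`,
#'   `src_type`, `dst_type`.
#' @export
read_network <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Hand-constructed simulation states for tests and examples
#'
#' \describe{
#'   \item{two-cells-one-edge}{Two osteocytes joined by one edge inside a
#'     deposited volume of 1e-3 mm^3 (flat front at 0.05 mm), one degree-0
#'     osteoblast: `q = 2000 /mm^3`, `k_ot = 1`, `M = 1000 /mm^3`.}
#'   \item{flat-120-blasts}{Flat front at 0, 120 degree-0 osteoblasts on a
#'     regular lattice, no osteocytes, no edges.}
#'   \item{steady-like}{A plausible mid-run state: front at 0.2 mm, 120
#'     osteoblasts with a mean degree of 1, 20 osteocytes sharing 120
#'     edges.}
#' }
#'
#' @param name Fixture name.
#' @return An `abm_state`.
#' @export
fixture_state <- function(name) {
  fixtures <- c("two-cells-one-edge", "flat-120-blasts", "steady-like")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  }
  p <- bone_params()
  base <- function(h0, ob, ot, edges, t) {
    structure(list(
      t = t, surface = height_field(p$L_y, h0 = h0), ob = ob, ot = ot,
      edges = edges, next_id = max(c(ob$id, ot$id)) + 1L,
      counters = c(connections = length(edges$src), burials = length(ot$id)),
      model = .model_from_params(p), derived = .derive_basic(p), L_z = p$L_z
    ), class = "abm_state")
  }
  if (name == "two-cells-one-edge") {
    # volume = L_z * h * L_y = 0.04 * 0.05 * 0.5 = 1e-3 mm^3
    return(base(
      h0 = 0.05,
      ob = list(id = 3L, y = 0.25, degree = 0L, born_t = 0),
      ot = list(id = 1:2, x = c(0.01, 0.03), y = c(0.2, 0.3),
                buried_t = c(10, 30), degree = c(1L, 1L)),
      edges = list(src = 2L, dst = 1L, t = 20), t = 50))
  }
  if (name == "flat-120-blasts") {
    n <- 120L
    return(base(
      h0 = 0,
      ob = list(id = seq_len(n), y = (seq_len(n) - 0.5) * p$L_y / n,
                degree = integer(n), born_t = numeric(n)),
      ot = list(id = integer(0), x = numeric(0), y = numeric(0),
                buried_t = numeric(0), degree = integer(0)),
      edges = list(src = integer(0), dst = integer(0), t = numeric(0)), t = 0))
  }
  # steady-like: deterministic construction with exact known metrics
  n <- 120L
  deg <- rep(c(0L, 1L, 2L), times = c(45L, 30L, 45L))  # mean degree 1
  n_ot <- 20L
  ot_id <- 1000L + seq_len(n_ot)
  src <- rep(seq_len(n), times = deg)                   # 90 osteoblast ends
  dst <- rep(ot_id, length.out = length(src))
  ot_deg <- tabulate(match(dst, ot_id), n_ot)
  base(
    h0 = 0.2,
    ob = list(id = seq_len(n), y = (seq_len(n) - 0.5) * p$L_y / n,
              degree = deg, born_t = numeric(n)),
    ot = list(id = ot_id, x = seq(0.005, 0.195, length.out = n_ot),
              y = rep(seq(0.05, 0.45, length.out = 5), 4),
              buried_t = seq(10, 290, length.out = n_ot), degree = ot_deg),
    edges = list(src = src, dst = dst, t = rep(150, length(src))), t = 300)
}

#' Write a complete, reproducible run artifact
#'
#' Persists a simulation run: per-interval summary table (`summary.csv`),
#' final network (`edges.csv` + `edges_nodes.csv`, and `network.graphml`),
#' final height field (`surface.csv`), optional height-field trajectory
#' (`surface_trajectory.csv`, long format `t,y,h_mm`), and a `metadata.dcf`
#' sidecar holding all parameters, derived constants, the seed and the
#' package version. Re-running with the stored parameters and seed
#' reproduces the summary table bit-for-bit.
#'
#' @param traj An `abm_trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifact <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(traj$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  export_network(traj$final_state, file.path(dir, "edges.csv"), "edge-csv")
  export_network(traj$final_state, file.path(dir, "network.graphml"), "graphml")
  surf <- traj$final_state$surface
  utils::write.csv(data.frame(y_mm = signif(surf$y, 9),
                              h_mm = signif(surf$h, 9)),
                   file.path(dir, "surface.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(traj$surfaces)) {
    long <- do.call(rbind, lapply(seq_along(traj$surfaces), function(i) {
      s <- traj$surfaces[[i]]
      data.frame(t = s$t, y_mm = signif(s$y, 9), h_mm = signif(s$h, 9))
    }))
    utils::write.csv(long, file.path(dir, "surface_trajectory.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  p <- traj$params
  d <- traj$derived
  meta <- c(
    vapply(.param_fields, function(f) as.character(p[[f]]), character(1)),
    kappa_form = format(d$kappa_form, digits = 17),
    v_wave = format(d$v_wave, digits = 17),
    n_osteoblasts = as.character(d$n_osteoblasts),
    package_version = as.character(utils::packageVersion("osteonet"))
  )
  names(meta)[seq_along(.param_fields)] <- .param_fields
  write.dcf(matrix(meta, nrow = 1, dimnames = list(NULL, names(meta))),
            file.path(dir, "metadata.dcf"))
  invisible(dir)
}
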