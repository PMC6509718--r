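#' Read a vessel network from a CSV edge list
#'
#' The edge-list dialect is a plain comma-separated file with one row per
#' segment and `#`-prefixed header records. Required columns:
#' `segment_id, node_a, node_b, xa, ya, za, xb, yb, zb, radius_um`; an
#' optional `length_um` column carries the geodesic length (filled with the
#' Euclidean endpoint distance when absent or empty). The domain box is given
#' either as a header record `# box Nx Ny Nz` (μm) or via the `box` argument;
#' the argument wins when both are present.
#'
#' @param path Path to the CSV file.
#' @param box Optional numeric length-3 domain extents (μm).
#' @param face_tol Face-tagging tolerance, μm.
#' @return A [vessel_network()].
#' @export
read_edge_list <- function(path, box = NULL, face_tol = 1.0) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^#", lines, value = TRUE)
  provenance <- ""
  for (h in headers) {
    body <- trimws(sub("^#+\\s*", "", h))
    if (grepl("^box\\b", body)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(sub("^box", "", body)),
                                                   "[,[:space:]]+")[[1]]))
      vals <- vals[!is.na(vals)]
      if (length(vals) != 3) stop("malformed '# box' header: ", h, call. = FALSE)
      if (is.null(box)) box <- vals
    } else if (grepl("^provenance\\b", body)) {
      provenance <- trimws(sub("^provenance", "", body))
    }
  }
  if (is.null(box)) {
    stop("no domain box: supply `box` or a '# box Nx Ny Nz' header", call. = FALSE)
  }
  body_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  required <- c("segment_id", "node_a", "node_b", "xa", "ya", "za",
                "xb", "yb", "zb", "radius_um")
  if (length(body_lines) == 0) {
    return(vessel_network(
      nodes = tibble::tibble(id = integer(), x = double(), y = double(), z = double()),
      segments = tibble::tibble(id = integer(), node_a = integer(),
                                node_b = integer(), radius = double(),
                                length = double()),
      box = box, provenance = provenance, face_tol = face_tol))
  }
  # base strtod parsing is correctly rounded, so %.17g output round-trips
  # bit-exactly
  df <- tryCatch(
    utils::read.csv(textConnection(paste(body_lines, collapse = "\n")),
                    colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("edge list missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(df) > 0) {
    for (col in c(required, intersect("length_um", names(df)))) {
      if (col %in% c("segment_id", "node_a", "node_b")) next
      if (!is.numeric(df[[col]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
        stop(sprintf("parse error in %s: non-numeric value in column %s (data row %d)",
                     path, col, if (is.na(bad)) 1L else bad), call. = FALSE)
      }
    }
    if (anyNA(df[required])) {
      bad <- which(rowSums(is.na(df[required])) > 0)[1]
      stop(sprintf("parse error in %s: missing value in data row %d", path, bad),
           call. = FALSE)
    }
  }
  for (col in setdiff(names(df), c("segment_id", "node_a", "node_b"))) {
    df[[col]] <- as.numeric(df[[col]])
  }

  # node table from endpoint coordinates keyed by node id
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(id = as.integer(df$node_a), x = df$xa, y = df$ya, z = df$za),
    tibble::tibble(id = as.integer(df$node_b), x = df$xb, y = df$yb, z = df$zb)
  ))
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) {
    stop("node id ", dup[1], " appears with inconsistent coordinates", call. = FALSE)
  }
  segments <- tibble::tibble(
    id = as.integer(df$segment_id),
    node_a = as.integer(df$node_a),
    node_b = as.integer(df$node_b),
    radius = df$radius_um,
    length = if ("length_um" %in% names(df)) df$length_um else NA_real_
  )
  vessel_network(nodes, segments, box = box, provenance = provenance,
                 face_tol = face_tol)
}

#' Write a vessel network to a CSV edge list
#'
#' Inverse of [read_edge_list()]: re-reading the written file reproduces the
#' node and segment tables and the box exactly (for finite decimal inputs,
#' full `%.17g` precision is used so the round trip is bit-exact).
#'
#' @param net A [vessel_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  nd <- net$nodes
  sg <- net$segments
  ia <- match(sg$node_a, nd$id)
  ib <- match(sg$node_b, nd$id)
  fmt <- function(x) sprintf("%.17g", x)
  header <- c(
    sprintf("# box %s %s %s", fmt(net$box[1]), fmt(net$box[2]), fmt(net$box[3])),
    if (nzchar(net$provenance)) paste("# provenance", net$provenance),
    "segment_id,node_a,node_b,xa,ya,za,xb,yb,zb,radius_um,length_um"
  )
  rows <- if (nrow(sg) > 0) {
    paste(sg$id, sg$node_a, sg$node_b,
          fmt(nd$x[ia]), fmt(nd$y[ia]), fmt(nd$z[ia]),
          fmt(nd$x[ib]), fmt(nd$y[ib]), fmt(nd$z[ib]),
          fmt(sg$radius), fmt(sg$length), sep = ",")
  } else character()
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Convert a vessel network to an igraph graph
#'
#' Vertices carry `name` (node id), `x`, `y`, `z`; edges carry `segment_id`,
#' `radius_um`, `length_um`, `component`; the graph carries the box extents as
#' attributes `box_x`, `box_y`, `box_z`.
#'
#' @param net A [vessel_network()].
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(net) {
  nd <- net$nodes
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(net$segments$node_a),
                   to = as.character(net$segments$node_b),
                   segment_id = net$segments$id,
                   radius_um = net$segments$radius,
                   length_um = net$segments$length,
                   # -1 encodes "unassigned": GraphML has no integer NA
                   component = ifelse(is.na(net$segments$component), -1L,
                                      net$segments$component)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$id),
                          x = nd$x, y = nd$y, z = nd$z)
  )
  g <- igraph::set_graph_attr(g, "box_x", unname(net$box[1]))
  g <- igraph::set_graph_attr(g, "box_y", unname(net$box[2]))
  g <- igraph::set_graph_attr(g, "box_z", unname(net$box[3]))
  igraph::set_graph_attr(g, "provenance", net$provenance)
}

#' Write a vessel network as GraphML
#' @param net A [vessel_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a vessel network from GraphML
#'
#' Expects the attribute names written by [write_graphml()].
#'
#' @param path GraphML file path.
#' @param box Optional box override (μm); defaults to the stored attributes.
#' @param face_tol Face-tagging tolerance, μm.
#' @return A [vessel_network()].
#' @export
read_graphml <- function(path, box = NULL, face_tol = 1.0) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(box)) {
    box <- c(igraph::graph_attr(g, "box_x"),
             igraph::graph_attr(g, "box_y"),
             igraph::graph_attr(g, "box_z"))
  }
  nd <- tibble::tibble(
    id = as.integer(igraph::V(g)$name),
    x = igraph::V(g)$x, y = igraph::V(g)$y, z = igraph::V(g)$z
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  comp <- igraph::edge_attr(g, "component")
  sg <- tibble::tibble(
    id = as.integer(igraph::edge_attr(g, "segment_id")),
    node_a = as.integer(el[, 1]),
    node_b = as.integer(el[, 2]),
    radius = as.numeric(igraph::edge_attr(g, "radius_um")),
    length = as.numeric(igraph::edge_attr(g, "length_um")),
    component = if (is.null(comp)) NA_integer_ else {
      comp <- as.integer(comp)
      ifelse(comp < 0, NA_integer_, comp)
    }
  )
  prov <- igraph::graph_attr(g, "provenance")
  vessel_network(nd, sg, box = box,
                 provenance = if (is.null(prov) || is.na(prov)) "" else prov,
                 face_tol = face_tol)
}
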