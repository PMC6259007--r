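#' Construct a symptom network
#'
#' A weighted undirected network of partial correlations: a symmetric weight
#' matrix with zero diagonal and entries in \[-1, 1\], plus node labels and
#' optional estimation metadata.
#'
#' @param weights symmetric numeric matrix (zero diagonal, entries in \[-1,1\]).
#' @param labels node labels; defaults to `colnames(weights)` or V1..Vp.
#' @param meta optional list of estimation metadata (correlation method,
#'   selected penalty, sample size, ...).
#' @return an object of class `symptom_network`.
#' @export
symptom_network <- function(weights, labels = NULL, meta = list()) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (p != ncol(weights)) stop_validation("weight matrix must be square")
  if (is.null(labels)) labels <- colnames(weights) %||% paste0("V", seq_len(p))
  if (length(labels) != p) stop_validation("need %d node labels", p)
  if (anyDuplicated(labels)) stop_validation("node labels must be unique")
  if (max(abs(weights - t(weights))) > 1e-12)
    stop_validation("weight matrix is not symmetric (tolerance 1e-12)")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0))
    stop_validation("weight matrix must have an exactly zero diagonal")
  if (max(abs(weights)) > 1 + 1e-12)
    stop_validation("edge weights must lie in [-1, 1]")
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights, meta = meta),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  ut <- upper.tri(x$weights)
  cat(sprintf("<symptom_network> %d nodes, %d edges\n",
              length(x$labels), sum(x$weights[ut] != 0)))
  if (!is.null(x$meta$lambda))
    cat(sprintf("lambda = %.4g, correlation = %s, n = %s\n",
                x$meta$lambda, x$meta$method %||% "?", x$meta$n %||% "?"))
  invisible(x)
}

n_nodes <- function(net) length(net$labels)

edge_pairs <- function(net) {
  p <- n_nodes(net)
  idx <- which(upper.tri(net$weights), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             node_i = net$labels[idx[, 1]], node_j = net$labels[idx[, 2]],
             weight = net$weights[idx], stringsAsFactors = FALSE)
}

edge_label <- function(a, b) paste(a, b, sep = "--")

#' Mean edge weight of a network
#'
#' Arithmetic mean of the p(p-1)/2 unique edge weights. By default the
#' structural zeros (absent edges) are included in the denominator, i.e. a
#' per-pair average over all node pairs; set `nonzero_only = TRUE` to average
#' only over present edges.
#'
#' @param network a [symptom_network()].
#' @param nonzero_only average over nonzero edges only (default `FALSE`).
#' @return mean edge weight (0 for an empty network).
#' @export
mean_edge_weight <- function(network, nonzero_only = FALSE) {
  stopifnot(inherits(network, "symptom_network"))
  if (n_nodes(network) < 2) stop_validation("need at least 2 nodes")
  w <- network$weights[upper.tri(network$weights)]
  if (nonzero_only) {
    w <- w[w != 0]
    if (!length(w)) return(0)
  }
  mean(w)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a network to file
#'
#' Supported formats: edge-list CSV (`node_i,node_j,weight` with a `# nodes:`
#' header line preserving isolated nodes), a JSON document with labels, the
#' full weight matrix and metadata, and GraphML. Weights are written with
#' full double precision so a write/read round trip reproduces the matrix to
#' 1e-12.
#'
#' @param network a [symptom_network()].
#' @param path output path; format inferred from extension
#'   (`.csv`, `.json`, `.graphml`/`.xml`) unless `format` is given.
#' @param format one of `"csv"`, `"json"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("auto", "csv", "json", "graphml")) {
  stopifnot(inherits(network, "symptom_network"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    csv = {
      ed <- edge_pairs(network)
      ed <- ed[ed$weight != 0, c("node_i", "node_j", "weight")]
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(paste0("# nodes: ", paste(network$labels, collapse = ",")),
                 con)
      writeLines("node_i,node_j,weight", con)
      if (nrow(ed))
        writeLines(paste(ed$node_i, ed$node_j, fmt_num(ed$weight), sep = ","),
                   con)
    },
    json = {
      doc <- list(labels = network$labels,
                  weights = unname(network$weights),
                  meta = network$meta)
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    },
    graphml = write_graphml(network, path)
  )
  invisible(path)
}

#' Read a network from file
#'
#' Counterpart of [write_network()]; the format is inferred from the file
#' extension unless given.
#'
#' @param path input path.
#' @param format one of `"csv"`, `"json"`, `"graphml"`.
#' @return a [symptom_network()].
#' @export
read_network <- function(path, format = c("auto", "csv", "json", "graphml")) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    csv = {
      lines <- readLines(path)
      if (!length(lines) || !startsWith(lines[1], "# nodes:"))
        stop_validation("malformed network CSV: missing '# nodes:' header")
      labels <- trimws(strsplit(sub("^# nodes:\\s*", "", lines[1]), ",")[[1]])
      w <- matrix(0, length(labels), length(labels),
                  dimnames = list(labels, labels))
      ed <- read.csv(text = paste(lines[-1], collapse = "\n"),
                     stringsAsFactors = FALSE)
      if (!all(c("node_i", "node_j", "weight") %in% names(ed)))
        stop_validation("malformed network CSV: bad edge columns")
      for (r in seq_len(nrow(ed))) {
        i <- match(ed$node_i[r], labels); j <- match(ed$node_j[r], labels)
        if (is.na(i) || is.na(j))
          stop_validation("edge references unknown node at line %d", r)
        w[i, j] <- w[j, i] <- ed$weight[r]
      }
      symptom_network(w, labels)
    },
    json = {
      doc <- jsonlite::read_json(path, simplifyVector = TRUE)
      if (is.null(doc$labels) || is.null(doc$weights))
        stop_validation("malformed network JSON")
      w <- as.matrix(doc$weights)
      symptom_network(w, as.character(doc$labels),
                      meta = as.list(doc$meta %||% list()))
    },
    graphml = read_graphml(path)
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", json = "json", graphml = "graphml", xml = "graphml",
    stop_validation("cannot infer network format from extension '.%s'", ext))
}

write_graphml <- function(network, path) {
  labs <- network$labels
  ed <- edge_pairs(network)
  ed <- ed[ed$weight != 0, , drop = FALSE]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"/>', labs),
    if (nrow(ed)) sprintf(
      '    <edge source="%s" target="%s"><data key="w">%s</data></edge>',
      ed$node_i, ed$node_j, fmt_num(ed$weight)),
    "  </graph>",
    "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

read_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_validation("malformed GraphML: %s",
                                                      conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  labels <- xml2::xml_attr(nodes, "id")
  if (!length(labels)) stop_validation("malformed GraphML: no nodes")
  w <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  for (e in edges) {
    i <- match(xml2::xml_attr(e, "source"), labels)
    j <- match(xml2::xml_attr(e, "target"), labels)
    if (is.na(i) || is.na(j))
      stop_validation("malformed GraphML: edge references unknown node")
    val <- as.numeric(xml2::xml_text(xml2::xml_find_first(e, ".//g:data", ns)))
    w[i, j] <- w[j, i] <- val
  }
  symptom_network(w, labels)
}
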