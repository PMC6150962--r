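#' Read a PPI network from a tab/space-delimited edge list
#'
#' Each non-comment, non-blank line holds two protein IDs and an optional
#' numeric weight, separated by tabs or spaces. Lines starting with `#` are
#' comments. The network is canonicalized on read: self-interactions are
#' dropped and duplicate pairs (in either order) are collapsed, keeping the
#' first occurrence's weight; the counts removed are reported via [message()].
#'
#' @param path Path to the edge-list file.
#' @param delimiter `"auto"` (any whitespace, the default), `"tab"` or
#'   `"space"`.
#' @return An undirected simple [igraph::graph] with vertex `name` attributes;
#'   edge attribute `weight` is present iff the file had a third column.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "A A", "A C"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g) # 2
#' @export
read_edge_list <- function(path, delimiter = c("auto", "tab", "space")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("edge-list file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warning("empty edge list: ", path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  split_re <- switch(delimiter, auto = "[ \t]+", tab = "\t", space = " +")
  toks <- strsplit(trimws(lines), split_re)
  nt <- lengths(toks)
  if (any(nt < 2)) {
    stop("malformed edge-list line ", lineno[which(nt < 2)[1]],
         " in ", path, ": fewer than 2 fields")
  }
  if (any(nt > 3)) {
    warning("lines with more than 3 columns; extra columns ignored")
  }
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  w <- NULL
  if (any(nt >= 3)) {
    w <- suppressWarnings(as.numeric(vapply(
      toks, function(t) if (length(t) >= 3) t[3] else NA_character_, "")))
  }
  build_network(u, v, w)
}

# Canonicalize endpoint vectors into a simple undirected igraph:
# drop self-loops, collapse duplicate unordered pairs (first weight wins).
build_network <- function(u, v, w = NULL, extra_nodes = character()) {
  self <- u == v
  if (any(self)) {
    message(sum(self), " self-interaction(s) removed")
    u <- u[!self]; v <- v[!self]
    if (!is.null(w)) w <- w[!self]
  }
  a <- pmin(u, v); b <- pmax(u, v)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate interaction(s) collapsed")
    a <- a[!dup]; b <- b[!dup]
    if (!is.null(w)) w <- w[!dup]
  }
  nodes <- sort(unique(c(a, b, extra_nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  if (!is.null(w) && any(!is.na(w))) igraph::E(g)$weight <- w
  g
}

#' Write a network as a canonical edge list
#'
#' One edge per line, endpoints in lexicographic order, tab separated, with a
#' third weight column iff the network is weighted. Lines are sorted so that
#' writing is deterministic and `read_edge_list(write_edge_list(g))`
#' round-trips.
#'
#' @param net An undirected [igraph::graph] with vertex names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) > 0) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    if ("weight" %in% igraph::edge_attr_names(net)) {
      lines <- paste(a, b, format(igraph::E(net)$weight, trim = TRUE,
                                  digits = 15), sep = "\t")
    } else {
      lines <- paste(a, b, sep = "\t")
    }
    lines <- sort(lines)
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a complex set (one complex per line)
#'
#' Members are whitespace-separated protein IDs; duplicate members within a
#' line are collapsed; lines with fewer than two distinct members are skipped
#' with a warning (a protein complex has at least two subunits).
#'
#' @param path Path to the complex-set file.
#' @return A list of character vectors (sorted member IDs), in file order.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("complex file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    warning("empty complex file: ", path)
    return(list())
  }
  cxs <- lapply(strsplit(trimws(lines), "[ \t]+"), function(m) sort(unique(m)))
  small <- lengths(cxs) < 2
  if (any(small)) {
    warning(sum(small), " line(s) with < 2 distinct members skipped")
    cxs <- cxs[!small]
  }
  cxs
}

#' Write a complex set (one complex per line)
#'
#' @param complexes List of character vectors of member IDs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path) {
  writeLines(vapply(complexes, function(m) paste(sort(unique(m)),
                                                 collapse = "\t"), ""), path)
  invisible(path)
}

#' Write embeddings in word2vec text format
#'
#' Header line `"N d"`, then one `"nodeID v1 ... vd"` line per node.
#'
#' @param emb Numeric matrix, one row per node, rownames are node IDs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1, function(r)
                     paste(format(r, trim = TRUE, digits = 17),
                           collapse = " "))), con)
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path Path written by [write_embeddings()] (or any word2vec text
#'   file).
#' @return Numeric matrix with node-ID rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
  toks <- strsplit(trimws(lines[-1]), "[ \t]+")
  ids <- vapply(toks, `[`, "", 1L)
  emb <- matrix(unlist(lapply(toks, function(t) as.numeric(t[-1]))),
                ncol = hdr[2], byrow = TRUE)
  rownames(emb) <- ids
  stopifnot(nrow(emb) == hdr[1])
  emb
}
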