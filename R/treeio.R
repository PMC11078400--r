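#' Parse a rooted bifurcating Newick tree
#'
#' Reads a single rooted, strictly bifurcating Newick tree with branch
#' lengths and converts it to the node-indexing convention used throughout
#' the package: leaves are numbered `1..L` in the order they appear in the
#' Newick string, internal nodes `L+1..N` in postorder, and the root is node
#' `N`. Edge quantities (branch length, conservation state, rate multiplier)
#' are attached to the edge *above* a node and indexed by the child node;
#' the root carries none.
#'
#' Quoted labels and square-bracket comments are accepted and stripped;
#' labels in the internal-node position (e.g. bootstrap values) are ignored.
#'
#' @param text A Newick string, or the path to a file containing one tree.
#' @return An object of class `phylogeny`: a list with elements `L`, `N`,
#'   `E`, `parent` (length-`N` integer, `NA` at the root), `children`
#'   (`N x 2` integer matrix, `NA` rows for leaves), `branch_length`
#'   (length-`N` numeric, `NA` at the root), `leaf_label`, `root`,
#'   and `postorder`.
#' @examples
#' phy <- parse_newick("((A:0.1,B:0.1):0.1,C:0.2);")
#' phy$L  # 3
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop("'text' must be a single character string")
  if (!grepl("[(;]", text)) {
    if (!file.exists(text)) stop("no such file and not a Newick string: ", text)
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)  # strip bracket comments
  # protect quoted labels (may contain spaces) behind placeholders
  quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
  restored <- character(0)
  if (length(quoted)) {
    restored <- gsub("^'|'$", "", quoted)
    for (i in seq_along(quoted))
      text <- sub(quoted[i], sprintf("QUOTEDLBL%dX", i), text, fixed = TRUE)
  }
  .check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr)) stop("malformed Newick: could not parse tree")
  if (length(restored)) {
    hit <- match(sprintf("QUOTEDLBL%dX", seq_along(restored)), tr$tip.label)
    tr$tip.label[hit[!is.na(hit)]] <- restored[!is.na(hit)]
  }
  as_phylogeny(tr)
}

# Cheap structural pre-scan so malformed input gets a character offset.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  if (!grepl(";", text))
    stop("malformed Newick: missing terminating ';' at character offset ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Convert an ape `phylo` tree to the package's indexed representation
#'
#' Validates that the tree is rooted, strictly bifurcating, and has strictly
#' positive branch lengths on every edge, then renumbers internal nodes in
#' postorder starting at `L+1` so the root is node `N`.
#'
#' @param tr An object of class `phylo` (see [ape::read.tree()]).
#' @return A `phylogeny` object; see [parse_newick()].
#' @export
as_phylogeny <- function(tr) {
  if (!inherits(tr, "phylo")) stop("'tr' must be a phylo object")
  L <- length(tr$tip.label)
  if (L < 2L) stop("tree must have at least 2 leaves")
  if (is.null(tr$edge.length))
    stop("validation error: tree has no branch lengths")
  if (!ape::is.rooted(tr))
    stop("validation error: tree is unrooted (root trifurcation)")
  ndesc <- tabulate(tr$edge[, 1], nbins = L + tr$Nnode)
  bad <- which(ndesc[(L + 1):(L + tr$Nnode)] != 2L)
  if (length(bad))
    stop("validation error: polytomy or unary node at internal node(s) ",
         paste(bad + L, collapse = ", "))
  if (anyNA(tr$edge.length) || any(tr$edge.length <= 0)) {
    off <- tr$edge[which(is.na(tr$edge.length) | tr$edge.length <= 0), 2]
    stop("validation error: missing or non-positive branch length above ",
         "node(s) ", paste(off, collapse = ", "),
         " (zero-length branches must be pre-collapsed)")
  }
  lab <- tr$tip.label
  if (anyDuplicated(lab) || any(!nzchar(lab)))
    stop("validation error: leaf labels must be unique and non-empty")

  N <- 2L * L - 1L
  ape_root <- L + 1L
  kids <- vector("list", N)
  for (e in seq_len(nrow(tr$edge)))
    kids[[tr$edge[e, 1]]] <- c(kids[[tr$edge[e, 1]]], tr$edge[e, 2])

  # iterative postorder over ape ids, preserving child order of the string
  post_ape <- integer(N)
  np <- 0L
  stack <- ape_root
  visited <- logical(N)
  while (length(stack)) {
    node <- stack[length(stack)]
    ch <- kids[[node]]
    if (is.null(ch) || visited[node]) {
      post_ape[np <- np + 1L] <- node
      stack <- stack[-length(stack)]
    } else {
      visited[node] <- TRUE
      stack <- c(stack, rev(ch))
    }
  }

  new_id <- integer(N)
  new_id[seq_len(L)] <- seq_len(L)
  next_int <- L
  for (node in post_ape)
    if (node > L) new_id[node] <- (next_int <- next_int + 1L)

  parent <- rep(NA_integer_, N)
  children <- matrix(NA_integer_, N, 2)
  blen <- rep(NA_real_, N)
  for (e in seq_len(nrow(tr$edge))) {
    pa <- new_id[tr$edge[e, 1]]
    chd <- new_id[tr$edge[e, 2]]
    parent[chd] <- pa
    blen[chd] <- tr$edge.length[e]
  }
  for (node in seq_len(N)) {
    ch <- kids[[node]]
    if (!is.null(ch)) children[new_id[node], ] <- new_id[ch]
  }

  phy <- structure(list(
    L = L, N = N, E = N - 1L,
    parent = parent, children = children, branch_length = blen,
    leaf_label = lab, root = N, postorder = new_id[post_ape]
  ), class = "phylogeny")
  validate_phylogeny(phy)
  phy
}

#' @export
print.phylogeny <- function(x, ...) {
  cat("phylogeny: ", x$L, " leaves, ", x$N, " nodes, ", x$E, " edges\n",
      sep = "")
  cat("  leaves: ", paste(utils::head(x$leaf_label, 5), collapse = ", "),
      if (x$L > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

validate_phylogeny <- function(phy) {
  stopifnot(phy$N == 2L * phy$L - 1L, phy$E == phy$N - 1L)
  if (!is.na(phy$parent[phy$root])) stop("root must have no parent")
  if (anyNA(phy$parent[-phy$root])) stop("non-root node lacks a parent")
  if (any(phy$branch_length[-phy$root] <= 0, na.rm = TRUE))
    stop("branch lengths must be positive")
  pos <- order(phy$postorder)  # pos[i] = position of node i
  ints <- which(!is.na(phy$children[, 1]))
  for (i in ints)
    if (any(pos[phy$children[i, ]] > pos[i]))
      stop("postorder violated: child after parent")
  invisible(phy)
}

#' Serialize a phylogeny back to Newick
#'
#' @param phy A `phylogeny` object.
#' @return A Newick string (with branch lengths, no internal labels).
#' @export
serialize_newick <- function(phy) {
  quote_if_needed <- function(lab) {
    if (grepl("[^A-Za-z0-9_.-]", lab)) paste0("'", lab, "'") else lab
  }
  rec <- function(node) {
    if (node <= phy$L) s <- quote_if_needed(phy$leaf_label[node])
    else s <- paste0("(", rec(phy$children[node, 1]), ",",
                     rec(phy$children[node, 2]), ")")
    if (node != phy$root)
      s <- paste0(s, ":", format(phy$branch_length[node], digits = 15))
    s
  }
  paste0(rec(phy$root), ";")
}

#' Build a balanced ultrametric binary tree
#'
#' Constructs the fully bifurcating tree used in the ideal-tree calibration
#' studies: `2^depth` leaves, every branch the same length, synthetic leaf
#' names `t1, t2, ...`.
#'
#' @param depth Integer >= 1; the tree has `2^depth` leaves.
#' @param branch_length Positive branch length shared by every edge.
#' @return A `phylogeny` object.
#' @examples
#' phy <- make_full_binary_tree(7, 0.1)  # 128 tips, root-to-tip 0.7
#' @export
make_full_binary_tree <- function(depth, branch_length) {
  if (length(depth) != 1L || is.na(depth) || depth < 1 || depth != round(depth))
    stop("'depth' must be a positive integer")
  if (length(branch_length) != 1L || is.na(branch_length) || branch_length <= 0)
    stop("'branch_length' must be positive")
  counter <- new.env()
  counter$i <- 0L
  bl <- format(branch_length, digits = 15)
  rec <- function(d) {
    if (d == 0L) {
      counter$i <- counter$i + 1L
      return(paste0("t", counter$i))
    }
    paste0("(", rec(d - 1L), ":", bl, ",", rec(d - 1L), ":", bl, ")")
  }
  parse_newick(paste0(rec(as.integer(depth)), ";"))
}

# ---------------------------------------------------------------------------
# neutral substitution model

#' Construct a neutral substitution model
#'
#' @param Q 4x4 instantaneous rate matrix over nucleotides A, C, G, T.
#'   Off-diagonals must be non-negative; rows must sum to zero. If rows sum
#'   to a small nonzero value the diagonal is reset to minus the off-diagonal
#'   row sum (with a warning).
#' @param pi Length-4 stationary distribution (positive, sums to 1).
#'   Stationarity `pi %*% Q = 0` is required within tolerance `1e-6`.
#' @return An object of class `neutral_model` with elements `Q` and `pi`.
#' @export
neutral_model <- function(Q, pi) {
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(4, 4))) stop("validation error: Q must be 4x4")
  pi <- as.numeric(pi)
  if (length(pi) != 4) stop("validation error: pi must have length 4")
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) stop("validation error: negative off-diagonal rate in Q")
  rs <- rowSums(Q)
  if (any(abs(rs) > 1e-8)) {
    warning("Q rows did not sum to 0 (max |sum| = ",
            format(max(abs(rs)), digits = 3),
            "); diagonal reset to minus the off-diagonal row sum")
    diag(Q) <- -rowSums(offd)
  }
  if (any(pi <= 0)) stop("validation error: pi entries must be positive")
  if (abs(sum(pi) - 1) > 1e-6)
    stop("validation error: pi must sum to 1 (got ", format(sum(pi)), ")")
  if (max(abs(pi %*% Q)) > 1e-6)
    stop("validation error: pi is not stationary for Q (max |pi Q| = ",
         format(max(abs(pi %*% Q)), digits = 3), ")")
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  names(pi) <- c("A", "C", "G", "T")
  structure(list(Q = Q, pi = pi), class = "neutral_model")
}

#' @export
print.neutral_model <- function(x, ...) {
  cat("neutral substitution model (A, C, G, T)\n")
  cat("pi:", format(x$pi, digits = 4), "\n")
  print(round(x$Q, 4))
  invisible(x)
}

#' Jukes-Cantor neutral model
#'
#' Uniform stationary distribution and equal exchange rates, scaled to one
#' expected substitution per unit branch length.
#' @return A `neutral_model`.
#' @export
neutral_model_jc <- function() {
  Q <- matrix(1 / 3, 4, 4)
  diag(Q) <- -1
  neutral_model(Q, rep(0.25, 4))
}

#' Bundled general-time-reversible neutral model
#'
#' A GTR model with unequal base frequencies (0.3, 0.2, 0.2, 0.3),
#' transition/transversion bias, and unit expected substitution rate at
#' stationarity, shipped as a phyloFit-style `.mod` file. Used as the
#' default background process in the simulation studies.
#' @return A `neutral_model`.
#' @export
neutral_model_gtr <- function() {
  parse_neutral_model(system.file("extdata", "neutral_gtr.mod",
                                  package = "cnelink", mustWork = TRUE))
}

#' Parse a neutral model from a phyloFit-style .mod file or plain text
#'
#' Two dialects are accepted. The phyloFit ".mod" dialect uses a
#' `BACKGROUND:` line with four frequencies and a `RATE_MAT:` keyword
#' followed by four rows of the 4x4 rate matrix. The plain-text fallback is
#' four frequencies on the first non-comment line followed by four matrix
#' rows. Nucleotide order is A, C, G, T in both cases.
#'
#' @param text File path or character vector of lines.
#' @return A `neutral_model`.
#' @export
parse_neutral_model <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else if (length(text) == 1L)
    text <- strsplit(text, "\n")[[1]]
  text <- sub("#.*$", "", text)
  numeric_tokens <- function(line) {
    toks <- regmatches(line, gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?", line))[[1]]
    as.numeric(toks)
  }
  if (any(grepl("RATE_MAT", text))) {
    bg_line <- grep("BACKGROUND", text, value = TRUE)
    if (!length(bg_line)) stop("validation error: no BACKGROUND line in .mod input")
    pi <- numeric_tokens(bg_line[1])
    if (length(pi) != 4)
      stop("validation error: BACKGROUND line must have 4 frequencies")
    i <- grep("RATE_MAT", text)[1]
    rows <- list()
    j <- i
    # RATE_MAT: may carry the first row on the same line
    first <- numeric_tokens(text[i])
    if (length(first) == 4) rows[[length(rows) + 1L]] <- first
    while (length(rows) < 4 && j < length(text)) {
      j <- j + 1
      v <- numeric_tokens(text[j])
      if (length(v) == 4) rows[[length(rows) + 1L]] <- v
      else if (length(v) > 0)
        stop("validation error: RATE_MAT row with ", length(v),
             " entries (matrix must be 4x4)")
    }
    if (length(rows) < 4) stop("validation error: RATE_MAT has fewer than 4 rows")
    Q <- do.call(rbind, rows)
  } else {
    vals <- unlist(lapply(text, numeric_tokens))
    if (length(vals) != 20)
      stop("validation error: plain-text model must contain exactly 20 ",
           "numbers (4 frequencies then a 4x4 matrix); got ", length(vals))
    pi <- vals[1:4]
    Q <- matrix(vals[5:20], 4, 4, byrow = TRUE)
  }
  neutral_model(Q, pi)
}
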