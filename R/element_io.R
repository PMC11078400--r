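#' Load one element: alignment plus trait vector, matched to a tree
#'
#' Builds the augmented data container used by the sampler: an `N x S`
#' nucleotide matrix whose top `L` rows are observed from the alignment and
#' whose remaining rows are latent ancestral sequences, together with a
#' length-`N` trait vector whose first `L` entries hold observed leaf values
#' (where available) and whose remaining entries are latent ancestral
#' values.
#'
#' Gaps (`-`, `.`), `N`, and IUPAC ambiguity codes are all treated as
#' missing data. Latent nucleotides (ancestral rows and missing leaf cells)
#' are initialized by sampling from the stationary distribution of `model`
#' (call `set.seed()` first for a reproducible initialization); latent trait
#' values are initialized to the mean of the observed trait values of
#' descendant leaves. Leaves absent from the trait table are flagged
#' unobserved and their trait value is treated as latent by the sampler.
#'
#' @param fasta Path to a FASTA alignment (one record per leaf species), or
#'   a named character vector of equal-length sequences.
#' @param trait Path to a tab-separated two-column table (species, value;
#'   header optional), or a data frame with those two columns. Species names
#'   must match tree leaf labels exactly (case-sensitive).
#' @param phylogeny A `phylogeny` from [parse_newick()].
#' @param model A `neutral_model`; its stationary distribution seeds the
#'   latent nucleotide initialization.
#' @return An object of class `element_data`: list with `X` (`N x S`
#'   integer matrix, codes 1..4 = A,C,G,T), `obs_mask` (`N x S` logical,
#'   `TRUE` where the entry is an observed leaf nucleotide), `S`, `y`,
#'   `observed_trait` (length-`L` logical), and `n_missing` (count of
#'   gap/ambiguity cells in the input alignment).
#' @export
load_element <- function(fasta, trait, phylogeny, model) {
  phy <- phylogeny
  seqs <- .read_alignment(fasta)
  if (anyDuplicated(names(seqs)))
    stop("duplicate species in alignment: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(unique(lens), collapse = ", "))
  unmatched <- setdiff(names(seqs), phy$leaf_label)
  if (length(unmatched))
    stop("alignment species not in tree: ", paste(unmatched, collapse = ", "))
  absent <- setdiff(phy$leaf_label, names(seqs))
  if (length(absent))
    stop("tree leaves missing from alignment: ",
         paste(absent, collapse = ", "))
  S <- unname(lens[1])
  if (S < 1) stop("alignment has no sites")

  code <- c(a = 1L, c = 2L, g = 3L, t = 4L)
  X <- matrix(NA_integer_, phy$N, S)
  for (i in seq_len(phy$L)) {
    v <- tolower(seqs[[phy$leaf_label[i]]])
    X[i, ] <- unname(code[v])  # anything not a/c/g/t -> NA (missing)
  }
  n_missing <- sum(is.na(X[seq_len(phy$L), , drop = FALSE]))
  obs_mask <- matrix(FALSE, phy$N, S)
  obs_mask[seq_len(phy$L), ] <- !is.na(X[seq_len(phy$L), , drop = FALSE])

  # latent initialization from the stationary distribution
  nlat <- sum(!obs_mask)
  X[!obs_mask] <- sample.int(4L, nlat, replace = TRUE, prob = model$pi)

  tt <- .read_trait_table(trait)
  if (anyDuplicated(tt$species))
    stop("duplicate species in trait table: ",
         paste(unique(tt$species[duplicated(tt$species)]), collapse = ", "))
  unmatched <- setdiff(tt$species, phy$leaf_label)
  if (length(unmatched))
    stop("trait species not in tree: ", paste(unmatched, collapse = ", "))
  y <- rep(NA_real_, phy$N)
  idx <- match(tt$species, phy$leaf_label)
  y[idx] <- tt$value
  observed_trait <- !is.na(y[seq_len(phy$L)])
  if (any(!is.finite(y[seq_len(phy$L)][observed_trait])))
    stop("non-finite trait value for an observed species")

  y <- .init_latent_traits(phy, y, observed_trait)

  structure(list(X = X, obs_mask = obs_mask, S = S, y = y,
                 observed_trait = observed_trait, n_missing = n_missing),
            class = "element_data")
}

# Midpoint-style initialization: each latent node takes the mean observed
# trait value over its descendant leaves (whole-tree mean as fallback).
.init_latent_traits <- function(phy, y, observed_trait) {
  obs_ids <- which(observed_trait)
  fallback <- if (length(obs_ids)) mean(y[obs_ids]) else 0
  sum_d <- numeric(phy$N)
  n_d <- numeric(phy$N)
  sum_d[obs_ids] <- y[obs_ids]
  n_d[obs_ids] <- 1
  for (node in phy$postorder) {
    if (node > phy$L) {
      ch <- phy$children[node, ]
      sum_d[node] <- sum(sum_d[ch])
      n_d[node] <- sum(n_d[ch])
    }
  }
  latent <- c(which(!observed_trait), (phy$L + 1L):phy$N)
  y[latent] <- ifelse(n_d[latent] > 0, sum_d[latent] / n_d[latent], fallback)
  y
}

.read_alignment <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    dna <- ape::read.FASTA(fasta)
    seqs <- lapply(as.character(dna), identity)
    names(seqs) <- names(dna)
    return(seqs)
  }
  if (is.character(fasta) && !is.null(names(fasta)))
    return(lapply(strsplit(tolower(fasta), ""), identity))
  stop("'fasta' must be a file path or a named character vector of sequences")
}

.read_trait_table <- function(trait) {
  if (is.data.frame(trait)) {
    if (ncol(trait) < 2) stop("trait table must have two columns")
    return(data.frame(species = as.character(trait[[1]]),
                      value = as.numeric(trait[[2]]),
                      stringsAsFactors = FALSE))
  }
  if (!file.exists(trait)) stop("no such trait file: ", trait)
  lines <- readLines(trait, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trait table")
  fields <- strsplit(lines, "\t")
  # header optional: drop the first row if its second field is not numeric
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_val)) fields <- fields[-1]
  if (!length(fields)) stop("trait table has no data rows")
  data.frame(species = vapply(fields, `[`, "", 1),
             value = as.numeric(vapply(fields, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' @export
print.element_data <- function(x, ...) {
  cat("element_data: S = ", x$S, " sites, ",
      sum(x$observed_trait), "/", length(x$observed_trait),
      " observed traits, ", x$n_missing, " missing alignment cells\n",
      sep = "")
  invisible(x)
}

#' Write an element (alignment + trait) to disk
#'
#' @param alignment Named character vector of sequences (one per species).
#' @param trait Named numeric vector of trait values.
#' @param fasta_path,trait_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_element <- function(alignment, trait, fasta_path, trait_path) {
  con <- file(fasta_path, "w")
  on.exit(close(con), add = TRUE)
  for (nm in names(alignment))
    writeLines(c(paste0(">", nm), alignment[[nm]]), con)
  utils::write.table(
    data.frame(species = names(trait), value = unname(trait)),
    trait_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(c(fasta_path, trait_path))
}
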