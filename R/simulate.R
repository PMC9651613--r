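# Synthetic bipartite DNA-protein benchmarks with planted latent structure.
#
# Positive links arise from a latent-factor model: each DNA and each protein
# carries a unit-norm factor vector, and a pair binds with probability
# plogis(scale * <z_d, z_p> + intercept), the intercept calibrated so the
# expected edge density hits the target. Shared factors induce the
# multi-hop shared-partner structure a path-based model can exploit.

#' Generate a synthetic DNA-protein binding benchmark
#'
#' @param n_dna,n_protein Node counts per class.
#' @param f Latent factor dimension (default 4).
#' @param density Target edge density rho over all DNA x protein pairs
#'   (default 0.05).
#' @param heldout_frac Fraction of positive links withheld from the graph
#'   (true planted links absent from the edge set; default 0.1).
#' @param scale Sharpness of the link-probability squash; larger values mean
#'   less label noise around the latent structure (default 6, a low-noise
#'   regime in which the planted signal is recoverable).
#' @param seed Seed fixing the whole dataset.
#' @return An object of class `synthetic_binding_data`: list with `graph`
#'   (an [interaction_graph()] containing the non-held-out positive edges),
#'   `examples` (kept positives plus matched corrupted negatives),
#'   `heldout` (held-out positives plus matched negatives), `factors`
#'   (latent factors, scale, intercept), `seed`.
#' @export
generate_binding_graph <- function(n_dna = 100L, n_protein = 100L, f = 4L,
                                   density = 0.05, heldout_frac = 0.1,
                                   scale = 6, seed = 1L) {
  stopifnot(n_dna >= 1L, n_protein >= 1L, f >= 1L,
            density > 0, density < 1, heldout_frac >= 0, heldout_frac < 1)
  set.seed(seed)
  unit_rows <- function(n) {
    z <- matrix(stats::rnorm(n * f), n, f)
    z / sqrt(rowSums(z^2))
  }
  Zd <- unit_rows(n_dna); Zp <- unit_rows(n_protein)
  S <- Zd %*% t(Zp)
  cal <- function(b) mean(stats::plogis(scale * S + b)) - density
  if (cal(-60) > 0 || cal(60) < 0)
    stop("density calibration infeasible at this scale")
  b <- stats::uniroot(cal, c(-60, 60), tol = 1e-10)$root
  P <- stats::plogis(scale * S + b)
  A <- matrix(stats::runif(length(P)) < P, n_dna, n_protein)

  dna_ids <- sprintf("dna%04d", seq_len(n_dna))
  prot_ids <- sprintf("prot%04d", seq_len(n_protein))
  pos_idx <- which(A, arr.ind = TRUE)
  if (nrow(pos_idx) == 0L) stop("no positive links drawn; density too low")
  pos <- data.frame(u = dna_ids[pos_idx[, 1L]], v = prot_ids[pos_idx[, 2L]],
                    label = 1L, stringsAsFactors = FALSE)

  n_hold <- floor(heldout_frac * nrow(pos))
  hold_rows <- if (n_hold > 0L) sample.int(nrow(pos), n_hold) else integer(0)
  held <- pos[hold_rows, , drop = FALSE]
  kept <- pos[setdiff(seq_len(nrow(pos)), hold_rows), , drop = FALSE]

  graph <- interaction_graph(c(dna_ids, prot_ids),
                             c(rep("DNA", n_dna), rep("PROTEIN", n_protein)),
                             as.matrix(kept[, c("u", "v")]))
  # all true positives (kept and held out) are off-limits as negatives;
  # drawn negatives are added to the forbidden set so matched negatives are
  # distinct pairs (cross-validation folds must never share an example)
  forbidden <- pair_keys(graph, pos$u, pos$v)
  corrupt_many <- function(df) {
    if (nrow(df) == 0L) return(df[0, , drop = FALSE])
    out <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      neg <- corrupt_negative(graph, df$u[i], df$v[i], forbidden)
      forbidden <<- c(forbidden, pair_keys(graph, neg$u, neg$v))
      out[[i]] <- neg
    }
    do.call(rbind, out)
  }
  examples <- rbind(kept, corrupt_many(kept))
  heldout <- rbind(held, corrupt_many(held))
  rownames(examples) <- NULL; rownames(heldout) <- NULL

  structure(list(graph = graph, examples = examples, heldout = heldout,
                 factors = list(dna = Zd, protein = Zp, scale = scale,
                                intercept = b, f = f, density = density),
                 seed = seed),
            class = "synthetic_binding_data")
}

#' @export
print.synthetic_binding_data <- function(x, ...) {
  cat("Synthetic DNA-protein benchmark (seed ", x$seed, ")\n", sep = "")
  print(x$graph)
  cat("  examples: ", sum(x$examples$label == 1L), " positives + ",
      sum(x$examples$label == 0L), " negatives; held out: ",
      sum(x$heldout$label == 1L), " positives\n", sep = "")
  invisible(x)
}

#' Latent-factor oracle score for a pair
#'
#' The planted-model score `plogis(scale * <z_u, z_v> + intercept)`; used to
#' verify that the benchmark is learnable (the oracle separates held-out
#' positives from matched negatives) before any model is blamed.
#'
#' @param data A `synthetic_binding_data` object.
#' @param pairs Data.frame with columns `u`, `v`.
#' @return Numeric vector of oracle probabilities.
#' @export
oracle_scores <- function(data, pairs) {
  fac <- data$factors
  getz <- function(id) {
    kind <- substr(id, 1L, 3L)
    num <- as.integer(sub("^[a-z]+", "", id))
    if (kind == "dna") fac$dna[num, ] else fac$protein[num, ]
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    stats::plogis(fac$scale * sum(getz(pairs$u[i]) * getz(pairs$v[i])) +
                  fac$intercept)
  }, numeric(1))
}

# conjoint-triad grouping of the 20 standard amino acids
AA_GROUPS <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
                  c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
                  c("R", "K"), c("D", "E"), c("C"))

#' Seven-group physicochemical composition of a protein sequence
#'
#' Amino acids are divided into seven physicochemical classes (the
#' conjoint-triad grouping: \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\},
#' \{R,K\}, \{D,E\}, \{C\}) and the sequence is summarized as the fraction
#' of residues in each class.
#'
#' @param sequence Amino-acid string over the 20 standard residues.
#' @param on_unknown `"error"` (default) or `"skip"` nonstandard residues.
#' @return Numeric vector of 7 fractions summing to 1.
#' @export
encode_protein_7group <- function(sequence, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  if (!nzchar(sequence)) stop("empty protein sequence")
  aa <- strsplit(toupper(sequence), "")[[1L]]
  grp <- rep(NA_integer_, length(aa))
  for (g in seq_along(AA_GROUPS)) grp[aa %in% AA_GROUPS[[g]]] <- g
  if (anyNA(grp)) {
    if (on_unknown == "error")
      stop("unknown residue(s): ", paste(unique(aa[is.na(grp)]), collapse = ""))
    grp <- grp[!is.na(grp)]
    if (length(grp) == 0L) stop("no standard residues in sequence")
  }
  tabulate(grp, 7L) / length(grp)
}

#' Normalized k-mer composition of a DNA sequence
#'
#' @param sequence Nucleotide string over A/C/G/T.
#' @param k Word length (1..4).
#' @param on_unknown `"error"` (default) or `"skip"` windows containing
#'   ambiguous bases.
#' @return Numeric vector of 4^k fractions (lexicographic k-mer order),
#'   summing to 1.
#' @export
encode_dna_kmer <- function(sequence, k = 3L,
                            on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  k <- as.integer(k)
  if (k < 1L || k > 4L) stop("k must be between 1 and 4")
  sequence <- toupper(sequence)
  if (nchar(sequence) < k) stop("sequence shorter than k")
  kmers <- substring(sequence, seq_len(nchar(sequence) - k + 1L),
                     seq_len(nchar(sequence) - k + 1L) + k - 1L)
  bases <- c("A", "C", "G", "T")
  all_k <- bases
  if (k > 1L) for (i in 2:k) all_k <- as.vector(outer(all_k, bases, paste0))
  all_k <- sort(all_k)
  idx <- match(kmers, all_k)
  if (anyNA(idx)) {
    if (on_unknown == "error")
      stop("ambiguous base in k-mer(s): ",
           paste(utils::head(unique(kmers[is.na(idx)]), 3L), collapse = ", "))
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) stop("no unambiguous k-mers in sequence")
  }
  tabulate(idx, length(all_k)) / length(idx)
}

#' Random sequences for the nodes of a synthetic benchmark
#'
#' Emits random DNA (length `dna_len`) and protein (length `prot_len`)
#' sequences keyed by node id, for exercising the sequence encoders and the
#' FASTA interface; the default model is structure-only and does not consume
#' them.
#'
#' @param data A `synthetic_binding_data` object.
#' @param dna_len,prot_len Sequence lengths.
#' @param seed Seed.
#' @return Named character vector (names are node ids).
#' @export
random_node_sequences <- function(data, dna_len = 100L, prot_len = 200L,
                                  seed = 1L) {
  set.seed(seed)
  g <- data$graph
  aa <- unlist(AA_GROUPS)
  out <- vapply(seq_along(g$nodes), function(i) {
    if (g$class[i] == "DNA")
      paste(sample(c("A", "C", "G", "T"), dna_len, replace = TRUE),
            collapse = "")
    else paste(sample(aa, prot_len, replace = TRUE), collapse = "")
  }, character(1))
  stats::setNames(out, g$nodes)
}

#' Write / read node sequences as FASTA
#'
#' Standard FASTA via Biostrings; record ids are node ids.
#' @param sequences Named character vector.
#' @param path File path.
#' @return `path` invisibly / a named character vector.
#' @export
write_node_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O")
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_node_fasta
#' @export
read_node_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O")
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}
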