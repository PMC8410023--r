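# HLA evolutionary divergence (HED): mean Grantham chemical distance
# between the peptide-binding-domain sequences of the two alleles at
# each class I locus.

# Grantham (1974) amino-acid distance table, the chemical distance
# combining composition, polarity and molecular volume, scaled so the
# mean over all residue pairs is 100. Stored as the published lower
# triangle in Grantham's residue order.
GRANTHAM_ORDER <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                    "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

GRANTHAM_LOWER <- list(
  S = c(R = 110, L = 145, P = 74, T = 58, A = 99, V = 124, G = 56,
        I = 142, F = 155, Y = 144, C = 112, H = 89, Q = 68, N = 46,
        K = 121, D = 65, E = 80, M = 135, W = 177),
  R = c(L = 102, P = 103, T = 71, A = 112, V = 96, G = 125, I = 97,
        F = 97, Y = 77, C = 180, H = 29, Q = 43, N = 86, K = 26,
        D = 96, E = 54, M = 91, W = 101),
  L = c(P = 98, T = 92, A = 96, V = 32, G = 138, I = 5, F = 22, Y = 36,
        C = 198, H = 99, Q = 113, N = 153, K = 107, D = 172, E = 138,
        M = 15, W = 61),
  P = c(T = 38, A = 27, V = 68, G = 42, I = 95, F = 114, Y = 110,
        C = 169, H = 77, Q = 76, N = 91, K = 103, D = 108, E = 93,
        M = 87, W = 147),
  T = c(A = 58, V = 69, G = 59, I = 89, F = 103, Y = 92, C = 149,
        H = 47, Q = 42, N = 65, K = 78, D = 85, E = 65, M = 81,
        W = 128),
  A = c(V = 64, G = 60, I = 94, F = 113, Y = 112, C = 195, H = 86,
        Q = 91, N = 111, K = 106, D = 126, E = 107, M = 84, W = 148),
  V = c(G = 109, I = 29, F = 50, Y = 55, C = 192, H = 84, Q = 96,
        N = 133, K = 97, D = 152, E = 121, M = 21, W = 88),
  G = c(I = 135, F = 153, Y = 147, C = 159, H = 98, Q = 87, N = 80,
        K = 127, D = 94, E = 98, M = 127, W = 184),
  I = c(F = 21, Y = 33, C = 198, H = 94, Q = 109, N = 149, K = 102,
        D = 168, E = 134, M = 10, W = 61),
  F = c(Y = 22, C = 205, H = 100, Q = 116, N = 158, K = 102, D = 177,
        E = 140, M = 28, W = 40),
  Y = c(C = 194, H = 83, Q = 99, N = 143, K = 85, D = 160, E = 122,
        M = 36, W = 37),
  C = c(H = 174, Q = 154, N = 139, K = 202, D = 154, E = 170, M = 196,
        W = 215),
  H = c(Q = 24, N = 68, K = 32, D = 81, E = 40, M = 87, W = 115),
  Q = c(N = 46, K = 53, D = 61, E = 29, M = 101, W = 130),
  N = c(K = 94, D = 23, E = 42, M = 142, W = 174),
  K = c(D = 101, E = 56, M = 95, W = 110),
  D = c(E = 45, M = 160, W = 181),
  E = c(M = 126, W = 152),
  M = c(W = 67)
)

grantham_matrix <- local({
  m <- matrix(0, 20, 20, dimnames = list(GRANTHAM_ORDER, GRANTHAM_ORDER))
  for (a in names(GRANTHAM_LOWER)) {
    v <- GRANTHAM_LOWER[[a]]
    m[a, names(v)] <- v
    m[names(v), a] <- v
  }
  m
})

#' Grantham chemical distance between amino acids
#'
#' Looks up the Grantham distance — a composite of composition,
#' polarity and molecular-volume differences — for pairs of standard
#' residues. Symmetric, zero on the diagonal. Vectorized over `a`/`b`.
#'
#' @param a,b One-letter amino-acid codes (case-insensitive).
#' @return Numeric vector of distances in Grantham units.
#' @examples
#' grantham_distance("S", "L") # 145
#' @export
grantham_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bad <- unique(c(a[!(a %in% GRANTHAM_ORDER)], b[!(b %in% GRANTHAM_ORDER)]))
  if (length(bad) > 0) {
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  grantham_matrix[cbind(a, b)]
}

#' Mean Grantham divergence between two aligned protein sequences
#'
#' The per-site mean of Grantham distances over aligned positions —
#' the sequence-level divergence underlying HED. Positions where either
#' sequence has a gap character (`-`, `.`, `*`) are excluded from both
#' numerator and denominator; `normalize = FALSE` returns the raw sum
#' instead of the mean.
#'
#' @param s1,s2 Amino-acid strings of equal aligned length.
#' @param normalize Divide by the number of compared (ungapped)
#'   positions (default `TRUE`).
#' @return Divergence in Grantham units (per site when normalized).
#' @export
sequence_divergence <- function(s1, s2, normalize = TRUE) {
  stopifnot(is.character(s1), is.character(s2),
            length(s1) == 1, length(s2) == 1)
  a <- strsplit(toupper(s1), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(s2), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences differ in length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  gap_chars <- c("-", ".", "*")
  keep <- !(a %in% gap_chars) & !(b %in% gap_chars)
  if (!any(keep)) {
    stop("no ungapped aligned positions; divergence undefined",
         call. = FALSE)
  }
  d <- grantham_distance(a[keep], b[keep])
  if (normalize) mean(d) else sum(d)
}

#' Read an HLA allele protein FASTA into an allele database
#'
#' Reads pre-aligned peptide-binding-domain sequences (class I: the
#' exon 2-3 protein region) with IMGT/HLA-style headers. The allele
#' name is taken as the first whitespace-separated token of each header
#' that contains a `*` (e.g. `A*01:01`), falling back to the first
#' token.
#'
#' @param path FASTA file of aligned allele protein sequences.
#' @return Named character vector: allele name -> sequence.
#' @export
read_allele_db <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  nm <- vapply(strsplit(headers, "\\s+"), function(tokens) {
    starred <- grep("\\*", tokens, value = TRUE)
    if (length(starred) > 0) starred[1] else tokens[1]
  }, character(1))
  db <- stats::setNames(as.character(seqs), nm)
  if (anyDuplicated(names(db))) {
    stop("duplicate allele names in ", path, call. = FALSE)
  }
  db
}

# reduce an allele name to two-field resolution (locus*group:protein)
two_field <- function(allele) {
  sub("^([^*]+\\*[0-9]+:[0-9]+).*$", "\\1", allele)
}

resolve_allele <- function(allele, allele_db) {
  if (allele %in% names(allele_db)) return(allele_db[[allele]])
  tf <- two_field(allele)
  db_tf <- two_field(names(allele_db))
  hit <- which(db_tf == tf)
  if (length(hit) == 0) {
    stop("allele ", allele, " not resolvable in the allele database ",
         "at two-field resolution", call. = FALSE)
  }
  allele_db[[hit[1]]]
}

#' Mean class I HLA evolutionary divergence of a genotype
#'
#' For each class I locus (A, B, C), HED is the mean per-site Grantham
#' distance between the peptide-binding-domain sequences of the two
#' alleles — zero for a homozygous locus. The individual-level summary
#' `mean_class1` is the arithmetic mean of the three locus values: a
#' sequence-based proxy for the breadth of the immunopeptidome the
#' genotype can present.
#'
#' Alleles are matched in `allele_db` at two-field resolution
#' (higher-field input names are truncated); an unresolvable allele is
#' an error, never silently replaced by a near neighbour.
#'
#' @param genotype Character vector of six allele names, in order A1,
#'   A2, B1, B2, C1, C2 (names, if present, are ignored).
#' @param allele_db Named character vector from [read_allele_db()].
#' @param normalize Passed to [sequence_divergence()].
#' @return An object of class `hed_result`: list with `per_locus`
#'   (named numeric, loci A/B/C) and `mean_class1`.
#' @export
mean_class1_hed <- function(genotype, allele_db, normalize = TRUE) {
  stopifnot(is.character(genotype), length(genotype) == 6,
            is.character(allele_db), !is.null(names(allele_db)))
  loci <- c("A", "B", "C")
  per_locus <- stats::setNames(numeric(3), loci)
  for (i in seq_along(loci)) {
    a1 <- resolve_allele(genotype[2 * i - 1], allele_db)
    a2 <- resolve_allele(genotype[2 * i], allele_db)
    per_locus[[i]] <- sequence_divergence(a1, a2, normalize = normalize)
  }
  structure(
    list(per_locus = per_locus, mean_class1 = mean(per_locus)),
    class = "hed_result"
  )
}

#' @export
print.hed_result <- function(x, ...) {
  cat(sprintf(
    "<hed_result> HED A %.3f, B %.3f, C %.3f; mean class I %.3f\n",
    x$per_locus[["A"]], x$per_locus[["B"]], x$per_locus[["C"]],
    x$mean_class1))
  invisible(x)
}

#' HED table for a cohort of genotypes
#'
#' Applies [mean_class1_hed()] to a genotype table (TSV path or data
#' frame with columns `individual_id`, `A1`, `A2`, `B1`, `B2`, `C1`,
#' `C2`).
#'
#' @param genotypes Data frame or TSV path.
#' @param allele_db Named character vector from [read_allele_db()].
#' @param normalize Passed to [sequence_divergence()].
#' @return Data frame: `individual_id`, `hed_A`, `hed_B`, `hed_C`,
#'   `mean_class1_hed`.
#' @export
hed_table <- function(genotypes, allele_db, normalize = TRUE) {
  if (is.character(genotypes)) {
    genotypes <- utils::read.delim(genotypes, sep = "\t", header = TRUE,
                                   colClasses = "character", quote = "",
                                   stringsAsFactors = FALSE)
  }
  required <- c("individual_id", "A1", "A2", "B1", "B2", "C1", "C2")
  if (!all(required %in% names(genotypes))) {
    stop("genotype table needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    hed <- mean_class1_hed(
      c(g$A1, g$A2, g$B1, g$B2, g$C1, g$C2), allele_db,
      normalize = normalize)
    data.frame(individual_id = g$individual_id,
               hed_A = hed$per_locus[["A"]],
               hed_B = hed$per_locus[["B"]],
               hed_C = hed$per_locus[["C"]],
               mean_class1_hed = hed$mean_class1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
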