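# Tag polymorphisms defining the five ABO haplotypes: each haplotype is
# marked by a single tag allele, O1 by the rs8176719 G-deletion.
abo_tags <- function() {
  c(O1 = "rs8176719_delG", O2 = "rs41302905_T", A1 = "rs2519093_T",
    A2 = "rs1053878_A", B = "rs8176743_T")
}

abo_haplotypes <- function() c("O1", "O2", "A1", "A2", "B")

# Accept either haplotype labels or rsID column names; return an n x 5
# integer matrix with columns O1, O2, A1, A2, B.
as_dosage_matrix <- function(d) {
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L, dimnames = list(NULL, names(d)))
  d <- as.matrix(as.data.frame(d)[, , drop = FALSE])
  tags <- abo_tags()
  cn <- colnames(d)
  mapped <- ifelse(cn %in% tags, names(tags)[match(cn, tags)], cn)
  colnames(d) <- mapped
  missing_cols <- setdiff(names(tags), mapped)
  if (length(missing_cols))
    stop("missing dosage column(s): ", paste(missing_cols, collapse = ", "))
  d <- d[, names(tags), drop = FALSE]
  if (any(is.na(d)) || any(d != round(d)) || any(d < 0) || any(d > 2))
    stop("dosages must be integers in {0, 1, 2}; round fractional ",
         "(imputed) dosages explicitly before calling")
  storage.mode(d) <- "integer"
  d
}

#' Infer ABO diplotypes from tag-polymorphism dosages
#'
#' Each of the five ABO haplotypes (O1, O2, A1, A2, B) is tagged by one
#' allele; a subject carries two haplotypes, so a dosage vector is
#' resolvable exactly when its five tag dosages sum to 2: a dosage of 2 at
#' one site means homozygous, two sites at dosage 1 mean a heterozygous
#' pair. Any other total (e.g. three tag alleles from best-guess imputed
#' genotypes) is flagged unresolved (`NA`).
#'
#' @param dosages a data frame, matrix or named vector of integer dosages
#'   in \{0, 1, 2\}, with columns named either by haplotype
#'   (`O1`, `O2`, `A1`, `A2`, `B`) or by tag rsID
#'   (`rs8176719_delG`, `rs41302905_T`, `rs2519093_T`, `rs1053878_A`,
#'   `rs8176743_T`).
#' @return a character vector of diplotypes like `"O1/A1"` (haplotypes in
#'   the fixed order O1, O2, A1, A2, B), `NA` where unresolved.
#' @export
infer_diplotype <- function(dosages) {
  d <- as_dosage_matrix(dosages)
  total <- rowSums(d)
  out <- rep(NA_character_, nrow(d))
  ok <- total == 2L
  if (any(ok)) {
    haps <- abo_haplotypes()
    out[ok] <- apply(d[ok, , drop = FALSE], 1L, function(row) {
      pair <- rep(haps, row)
      paste(pair, collapse = "/")
    })
  }
  out
}

#' Additive haplotype coding with O1 reference
#'
#' Converts resolved diplotypes into counts of A1, A2, B and O2 haplotypes
#' (each 0-2); the O1 count is implicit (2 minus the sum), so O1/O1 is the
#' zero vector and effects estimated on this coding are per-haplotype-copy
#' contrasts against O1.
#'
#' @param diplotypes character vector as returned by [infer_diplotype()].
#' @return an integer matrix with columns `A1`, `A2`, `B`, `O2`.
#' @export
abo_additive <- function(diplotypes) {
  if (anyNA(diplotypes))
    stop("unresolved diplotype(s): exclude before additive coding")
  parts <- strsplit(diplotypes, "/", fixed = TRUE)
  bad <- vapply(parts, function(p)
    length(p) != 2L || !all(p %in% abo_haplotypes()), logical(1L))
  if (any(bad)) stop("malformed diplotype label(s)")
  counted <- c("A1", "A2", "B", "O2")
  out <- t(vapply(parts, function(p)
    vapply(counted, function(h) sum(p == h), integer(1L)), integer(4L)))
  colnames(out) <- counted
  out
}

#' Read a genotype-dosage file
#'
#' CSV with `subject_id` plus the five tag-rsID columns of integer dosages.
#'
#' @param path CSV file path.
#' @return a data frame with `subject_id` and dosage columns renamed to
#'   haplotype labels.
#' @export
read_dosages <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("dosage file lacks subject_id")
  d <- as_dosage_matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  cbind(data.frame(subject_id = df$subject_id, stringsAsFactors = FALSE),
        as.data.frame(d))
}
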