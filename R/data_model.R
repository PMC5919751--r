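# Domain containers and plain-text readers/writers.
#
# The atomic observation is the per-individual, per-site vector of base
# counts (A,C,G,T). A site_table holds those counts for all configured
# individuals at a set of sites, as a sites x individuals x 4 array, which
# keeps every downstream step vectorised.

#' Site-by-individual base-count table
#'
#' @param chrom character vector of chromosome names (one per site).
#' @param pos integer vector of 1-based positions.
#' @param counts numeric array `sites x individuals x 4`, base order
#'   A, C, G, T; non-negative integers.
#' @param individuals character vector of individual IDs (one per column).
#' @return object of class `site_table` with elements `chrom`, `pos`,
#'   `counts`, `individuals`.
#' @export
site_table <- function(chrom, pos, counts, individuals) {
  stopifnot(length(chrom) == length(pos))
  if (length(dim(counts)) != 3L || dim(counts)[3] != 4L)
    stop("counts must be a sites x individuals x 4 array")
  if (dim(counts)[1] != length(pos) || dim(counts)[2] != length(individuals))
    stop("counts dimensions do not match sites/individuals")
  if (length(counts) && min(counts) < 0) stop_parse("negative base count")
  if (is.double(counts) && length(counts) &&
      any(counts != round(counts))) stop_parse("non-integer base count")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 counts = counts, individuals = individuals),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites, %d individuals\n",
              length(x$pos), length(x$individuals)))
  invisible(x)
}

#' Number of sites in a site_table
#' @param x a `site_table`.
#' @export
n_sites <- function(x) length(x$pos)

#' Per-individual sequencing depth matrix
#' @param x a `site_table`.
#' @return numeric matrix `sites x individuals` of total read counts.
#' @export
depth_matrix <- function(x) {
  d <- x$counts[, , 1, drop = FALSE] + x$counts[, , 2, drop = FALSE] +
    x$counts[, , 3, drop = FALSE] + x$counts[, , 4, drop = FALSE]
  dim(d) <- dim(x$counts)[1:2]
  colnames(d) <- x$individuals
  d
}

subset_sites <- function(x, keep) {
  site_table(x$chrom[keep], x$pos[keep],
             x$counts[keep, , , drop = FALSE], x$individuals)
}

#' Population configuration for the four(+1)-population tree
#'
#' Maps individual IDs to the populations H1..H4 of the hypothesised tree
#' (((H1,H2)H3)H4), optionally an external population H5, an optional
#' error-estimation trio (roles T = error-prone target, R = error-free
#' reference, O = outgroup) and the genomic block size used by the
#' jackknife.
#'
#' @param H1,H2,H3,H4 character vectors of individual IDs (each non-empty).
#' @param H5 optional character vector for the external population.
#' @param error_trio optional named list/character with elements `T`, `R`,
#'   `O` giving individual IDs.
#' @param block_size genomic block length in bp (default 5 Mb).
#' @return object of class `pop_config`.
#' @export
pop_config <- function(H1, H2, H3, H4, H5 = NULL, error_trio = NULL,
                       block_size = 5e6) {
  pops <- list(H1 = as.character(H1), H2 = as.character(H2),
               H3 = as.character(H3), H4 = as.character(H4))
  if (!is.null(H5)) pops$H5 <- as.character(H5)
  if (any(lengths(pops[1:4]) < 1))
    stop_config("each of H1..H4 needs at least one individual")
  all_ids <- unlist(pops, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop_config("an individual may belong to exactly one population: ",
                paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(list(populations = pops, N = lengths(pops),
                 error_trio = error_trio,
                 block_size = as.numeric(block_size)),
            class = "pop_config")
}

#' @export
print.pop_config <- function(x, ...) {
  cat("pop_config:\n")
  for (p in names(x$populations))
    cat(sprintf("  %s: %s\n", p, paste(x$populations[[p]], collapse = ", ")))
  cat(sprintf("  block size: %g bp\n", x$block_size))
  invisible(x)
}

#' Read a population configuration from JSON
#'
#' Expected shape: `{"populations": {"H1": [...], ...},
#' "block_size": 5e6, "error_trio": {"T": "...", "R": "...", "O": "..."}}`.
#'
#' @param path path to a JSON file.
#' @return a [pop_config()] object.
#' @export
read_pop_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pops <- cfg$populations
  for (h in c("H1", "H2", "H3", "H4"))
    if (is.null(pops[[h]])) stop_config("config missing population ", h)
  pop_config(H1 = pops$H1, H2 = pops$H2, H3 = pops$H3, H4 = pops$H4,
             H5 = pops$H5,
             error_trio = cfg$error_trio,
             block_size = cfg$block_size %||% 5e6)
}

#' Read a long-format base-count TSV
#'
#' Columns `chrom pos individual nA nC nG nT`, tab- or space-separated,
#' `#` comment lines ignored. One row per (site, individual); individuals
#' missing at a site get zero counts.
#'
#' @param path input file path.
#' @param individuals optional character vector fixing the individual order
#'   (and the permitted IDs); defaults to order of first appearance.
#' @return a [site_table()].
#' @export
read_count_tsv <- function(path, individuals = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("^chrom\\b", lines[1])) {
    lineno <- lineno[-1]; lines <- lines[-1]
  }
  if (!length(lines)) {
    return(site_table(character(), integer(),
                      array(0, c(0, length(individuals %||% character()), 4)),
                      individuals %||% character()))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop_parse("line ", lineno[which(nf != 7L)[1]],
               ": expected 7 fields, got ", nf[nf != 7L][1])
  m <- matrix(unlist(fields), ncol = 7, byrow = TRUE)
  cnt <- suppressWarnings(matrix(as.numeric(m[, 4:7]), ncol = 4))
  if (anyNA(cnt) || any(cnt != round(cnt)))
    stop_parse("line ", lineno[which(rowSums(is.na(cnt) | cnt != round(cnt)) > 0)[1]],
               ": non-integer base count")
  if (any(cnt < 0))
    stop_parse("line ", lineno[which(rowSums(cnt < 0) > 0)[1]],
               ": negative base count")
  ids <- m[, 3]
  if (is.null(individuals)) {
    individuals <- unique(ids)
  } else if (!all(ids %in% individuals)) {
    stop_config("unknown individual ID: ",
                paste(unique(setdiff(ids, individuals)), collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop_parse("line ", lineno[which(is.na(pos))[1]],
                             ": non-integer position")
  key <- paste(m[, 1], pos, sep = "\r")
  ukey <- unique(key)
  si <- match(key, ukey)
  ii <- match(ids, individuals)
  a <- array(0, c(length(ukey), length(individuals), 4))
  a[cbind(rep(si, 4), rep(ii, 4), rep(1:4, each = length(si)))] <- as.vector(cnt)
  first <- !duplicated(key)
  site_table(m[first, 1], pos[first], a, individuals)
}

#' Write a site_table as a long-format count TSV
#'
#' Inverse of [read_count_tsv()]; rows with zero depth are kept so the
#' round trip is the identity.
#'
#' @param x a `site_table`.
#' @param path output file path.
#' @export
write_count_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chrom\tpos\tindividual\tnA\tnC\tnG\tnT", con)
  ns <- n_sites(x)
  if (ns == 0) return(invisible(path))
  for (j in seq_along(x$individuals)) {
    cat(sprintf("%s\t%d\t%s\t%d\t%d\t%d\t%d\n",
                x$chrom, x$pos, x$individuals[j],
                as.integer(x$counts[, j, 1]), as.integer(x$counts[, j, 2]),
                as.integer(x$counts[, j, 3]), as.integer(x$counts[, j, 4])),
        file = con, sep = "")
  }
  invisible(path)
}

# Decode one pileup base string + quality string into a length-4 count
# vector, honouring start (^X), end ($), indel (+n/-n...), deletion (*)
# and reference (., ,) symbols. Bases under quality < min_q are dropped.
decode_pileup_bases <- function(bases, quals, ref_idx, min_q) {
  out <- numeric(4)
  bs <- strsplit(bases, "")[[1]]
  qs <- strsplit(quals, "")[[1]]
  qi <- 0L
  i <- 1L
  nb <- length(bs)
  while (i <= nb) {
    ch <- bs[i]
    if (ch == "^") {          # read start: next char is mapping quality
      i <- i + 2L
    } else if (ch == "$") {   # read end mark
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {  # indel: length digits then seq
      j <- i + 1L
      while (j <= nb && grepl("[0-9]", bs[j])) j <- j + 1L
      len <- as.integer(paste(bs[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else {
      qi <- qi + 1L
      if (qi > length(qs)) stop_parse("pileup bases/qualities out of sync")
      q <- utf8ToInt(qs[qi]) - 33L
      if (ch == "." || ch == ",") {
        if (q >= min_q) {
          if (is.na(ref_idx)) return(NULL)  # ref N observed as '.'
          out[ref_idx] <- out[ref_idx] + 1
        }
      } else if (ch %in% c("*", "N", "n", ">", "<")) {
        # deletion/skip placeholders consume a quality, contribute nothing
      } else {
        b <- match(toupper(ch), BASES)
        if (!is.na(b) && q >= min_q) out[b] <- out[b] + 1
      }
      i <- i + 1L
    }
  }
  out
}

#' Parse samtools mpileup text into base counts
#'
#' Reads multi-sample `samtools mpileup` output (columns: chrom, pos, ref,
#' then per sample depth/bases/qualities). Reference-matching symbols
#' (`.`/`,`) are attributed to the reference base, start/end marks and
#' indel spans are skipped, and bases whose Phred quality (ASCII-33) is
#' below `min_base_quality` are excluded. Sites with reference `N` whose
#' only observations are reference matches are dropped with a warning.
#' Per-read mapping quality is not present in pileup text, so any mapping
#' quality filter must be applied upstream (e.g. `samtools mpileup -q 30`).
#'
#' @param path file path (or a character vector of pileup lines).
#' @param individuals IDs for the sample columns, in file order.
#' @param min_base_quality minimum Phred base quality (default 20).
#' @return a [site_table()].
#' @export
parse_mpileup <- function(path, individuals, min_base_quality = 20) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  nind <- length(individuals)
  want <- 3L + 3L * nind
  chrom <- character(0); pos <- integer(0)
  rows <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t")[[1]]
    if (length(f) != want)
      stop_parse("line ", k, ": expected ", want, " columns, got ", length(f))
    ref_idx <- match(toupper(f[3]), BASES)
    cnts <- matrix(0, nind, 4)
    dropped <- FALSE
    for (j in seq_len(nind)) {
      b <- f[3L + 3L * (j - 1L) + 2L]
      q <- f[3L + 3L * (j - 1L) + 3L]
      if (f[3L + 3L * (j - 1L) + 1L] == "0" || b == "*") next
      dec <- decode_pileup_bases(b, q, ref_idx, min_base_quality)
      if (is.null(dec)) { dropped <- TRUE; break }
      cnts[j, ] <- dec
    }
    if (dropped) {
      warning("site ", f[1], ":", f[2],
              " dropped: reference N with reference-matching observations")
      next
    }
    chrom <- c(chrom, f[1]); pos <- c(pos, as.integer(f[2]))
    rows[[length(rows) + 1L]] <- cnts
  }
  a <- array(0, c(length(rows), nind, 4))
  for (i in seq_along(rows)) a[i, , ] <- rows[[i]]
  site_table(chrom, pos, a, individuals)
}

#' Genotype matrix (allele-A dosages)
#'
#' @param genotypes integer matrix `individuals x sites` with entries in
#'   `{0,1,2}` (count of the focal allele; `NA` = missing).
#' @param positions integer site coordinates (1-based).
#' @param chrom chromosome label (single value or per-site vector).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, positions, chrom = "sim") {
  stopifnot(ncol(genotypes) == length(positions))
  if (any(!genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must lie in {0,1,2}")
  structure(list(genotypes = genotypes,
                 positions = as.integer(positions),
                 chrom = rep_len(as.character(chrom), length(positions))),
            class = "genotype_matrix")
}

#' Read ms/msms-format haplotype output
#'
#' Parses the standard coalescent-simulator text format: replicates are
#' separated by `//`, each with `segsites:` and `positions:` lines followed
#' by 0/1 haplotype rows. Consecutive groups of `ploidy` haplotypes are
#' summed into genotypes; fractional positions are mapped to integer
#' coordinates via `floor(pos * region_length) + 1`, keeping the first of
#' any colliding pair.
#'
#' @param path file path or character vector of lines.
#' @param ploidy haplotypes per individual (default 2).
#' @param region_length length in bp used to scale positions (default 5e6).
#' @return list of [genotype_matrix()] objects, one per replicate.
#' @export
read_ms <- function(path, ploidy = 2, region_length = 5e6) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  reps <- which(trimws(lines) == "//")
  out <- vector("list", length(reps))
  bounds <- c(reps, length(lines) + 1L)
  for (r in seq_along(reps)) {
    blk <- lines[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    blk <- blk[nzchar(trimws(blk))]
    ss_line <- grep("^segsites:", blk, value = TRUE)
    if (!length(ss_line)) stop_parse("replicate ", r, ": missing segsites")
    segsites <- as.integer(sub("^segsites:\\s*", "", ss_line[1]))
    if (segsites == 0L) {
      out[[r]] <- genotype_matrix(matrix(integer(0), 0, 0), integer(0))
      next
    }
    pos_line <- grep("^positions:", blk, value = TRUE)
    if (!length(pos_line)) stop_parse("replicate ", r, ": missing positions")
    posf <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "", pos_line[1])),
                                "\\s+")[[1]])
    if (any(posf < 0 | posf > 1))
      stop_parse("replicate ", r, ": position outside [0,1]")
    hap_lines <- blk[grepl("^[01]+$", blk)]
    if (length(hap_lines) %% ploidy != 0L)
      stop_parse("replicate ", r, ": ", length(hap_lines),
                 " haplotypes not divisible by ploidy ", ploidy)
    H <- matrix(as.integer(unlist(strsplit(hap_lines, ""))),
                nrow = length(hap_lines), byrow = TRUE)
    nind <- nrow(H) / ploidy
    G <- matrix(0L, nind, segsites)
    for (p in seq_len(ploidy))
      G <- G + H[seq(p, nrow(H), by = ploidy), , drop = FALSE]
    ipos <- as.integer(floor(posf * region_length)) + 1L
    keep <- !duplicated(ipos)
    out[[r]] <- genotype_matrix(G[, keep, drop = FALSE], ipos[keep])
  }
  out
}

#' Restrict to sites usable by the D-statistic
#'
#' Keeps only sites at which every one of H1..H4 (and H5, when configured)
#' has pooled read depth of at least `min_depth`; individuals with zero
#' reads at a retained site stay in the table with zero counts. Input must
#' be coordinate sorted.
#'
#' @param x a [site_table()].
#' @param config a [pop_config()].
#' @param min_depth minimum pooled per-population depth (default 1).
#' @return filtered `site_table`.
#' @export
intersect_sites <- function(x, config, min_depth = 1) {
  subset_sites(x, intersect_mask(x, config, min_depth))
}

# Logical keep-mask of intersect_sites (callers that carry parallel
# per-site structures, e.g. genotype matrices, subset with the mask).
intersect_mask <- function(x, config, min_depth = 1) {
  check_sorted(x)
  ids <- unlist(config$populations, use.names = FALSE)
  missing <- setdiff(ids, x$individuals)
  if (length(missing))
    stop_config("individuals in config absent from data: ",
                paste(missing, collapse = ", "))
  d <- depth_matrix(x)
  keep <- rep(TRUE, n_sites(x))
  for (p in names(config$populations)) {
    cols <- match(config$populations[[p]], x$individuals)
    pd <- rowSums(d[, cols, drop = FALSE])
    keep <- keep & pd >= min_depth
  }
  keep
}

check_sorted <- function(x) {
  if (n_sites(x) < 2) return(invisible(TRUE))
  ch <- factor(x$chrom, levels = unique(x$chrom))
  o <- order(as.integer(ch), x$pos)
  if (any(o != seq_along(o))) {
    bad <- which(o != seq_along(o))[1]
    stop_parse("input not coordinate-sorted at ", x$chrom[bad], ":", x$pos[bad])
  }
  invisible(TRUE)
}

#' Assign genomic block indices
#'
#' Blocks are `block_size`-bp windows counted from position 1 on each
#' chromosome; block boundaries fall at multiples of `block_size`.
#'
#' @param chrom,pos site coordinates.
#' @param block_size block length in bp.
#' @return integer block index per site (unique across chromosomes).
#' @export
block_index <- function(chrom, pos, block_size = 5e6) {
  within <- (as.numeric(pos) - 1) %/% as.numeric(block_size)
  ch <- as.integer(factor(chrom, levels = unique(chrom)))
  key <- ch * 2^40 + within       # exact in doubles for any real genome
  match(key, unique(key))
}
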