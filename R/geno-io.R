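#' Read SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (GT genotypes, optional per-call DP read depth) into
#' a [geno_matrix()]. One SNP locus is created per record, named from the ID
#' column (falling back to `CHROM_POS`); the allele registry is REF plus all
#' ALT alleles. `./.` and `.|.` genotypes become missing calls.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return A [geno_matrix()] of SNP loci.
#' @details Multi-allelic records are accepted with a warning (the target
#'   panels are bi-allelic). Non-diploid GT fields are an error.
#' @export
read_snp_vcf <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no variant records")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate locus IDs in VCF")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF '", path, "' has no GT field")
  dp <- if ("DP" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  } else NULL

  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) warning("multi-allelic record(s): ", paste(ids[multi], collapse = ", "))
  registries <- lapply(seq_len(nrow(fix)), function(i) {
    unname(c(fix[i, "REF"], strsplit(alt[i], ",", fixed = TRUE)[[1]]))
  })

  inds <- colnames(gt)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    g <- gt[i, ]
    parts <- strsplit(g, "[/|]")
    a1 <- a2 <- rep(NA_character_, length(inds))
    for (j in seq_along(parts)) {
      p <- parts[[j]]
      if (length(p) == 1 && (is.na(p) || p == ".")) next
      if (length(p) != 2) {
        stop("non-diploid genotype '", g[j], "' at locus ", ids[i],
             " for individual ", inds[j])
      }
      if (any(p == ".")) next # treat any half call as missing (atomic)
      idx <- as.integer(p) + 1L
      if (any(is.na(idx)) || any(idx > length(registries[[i]]))) {
        stop("allele index out of range in genotype '", g[j], "' at locus ", ids[i])
      }
      a1[j] <- registries[[i]][idx[1]]
      a2[j] <- registries[[i]][idx[2]]
    }
    rows[[i]] <- tibble::tibble(
      individual = inds, locus = ids[i], a1 = a1, a2 = a2,
      depth = if (is.null(dp)) NA_integer_ else as.integer(dp[i, ])
    )
  }
  loci_tbl <- tibble::tibble(locus = ids, kind = "SNP", alleles = registries)
  geno_matrix(dplyr::bind_rows(rows), loci = loci_tbl, individuals = inds)
}

#' Write SNP genotypes to a VCF file
#'
#' Serialises the SNP loci of a genotype matrix as minimal VCF 4.2 (GT and,
#' where present, DP). The inverse of [read_snp_vcf()] up to header detail.
#'
#' @param x A [geno_matrix()]; only its SNP loci are written.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(x, path) {
  snp <- x$loci[x$loci$kind == "SNP", ]
  if (nrow(snp) == 0) stop("no SNP loci to write")
  has_depth <- any(!is.na(x$calls$depth[x$calls$locus %in% snp$locus]))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_depth) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            x$individuals), collapse = "\t")
  )
  cm <- x$calls
  lines <- vapply(seq_len(nrow(snp)), function(i) {
    loc <- snp$locus[i]
    reg <- snp$alleles[[i]]
    cc <- cm[cm$locus == loc, ][match(x$individuals, cm$individual[cm$locus == loc]), ]
    cc <- cm[cm$locus == loc, ]
    cc <- cc[match(x$individuals, cc$individual), ]
    gt <- ifelse(
      is.na(cc$a1), "./.",
      paste0(match(cc$a1, reg) - 1L, "/", match(cc$a2, reg) - 1L)
    )
    field <- if (has_depth) {
      paste0(gt, ":", ifelse(is.na(cc$depth), ".", cc$depth))
    } else gt
    paste(c(paste0("ctg", i), i, loc, reg[1],
            if (length(reg) > 1) paste(reg[-1], collapse = ",") else ".",
            ".", "PASS", ".", if (has_depth) "GT:DP" else "GT", field),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read SSR genotypes from a GenePop or CSV table
#'
#' SSR alleles are PCR fragment lengths in base pairs. The GenePop dialect is
#' the standard 3-digit coding (six characters per genotype, `000` = missing
#' allele); 2-digit files are rejected. The CSV dialect has an `individual`
#' column followed by one column per locus with cells `"a/b"` or `"-"` for
#' missing.
#'
#' @param path Path to the genotype table.
#' @param dialect `"genepop"` or `"csv"`.
#' @return A [geno_matrix()]. For GenePop input the population blocks are
#'   attached as a [pop_map] in attribute `"popmap"`.
#' @export
read_ssr_table <- function(path, dialect = c("genepop", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") read_ssr_csv(path) else read_ssr_genepop(path)
}

read_ssr_csv <- function(path) {
  tbl <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!nrow(tbl)) stop("empty genotype table: ", path)
  id_col <- names(tbl)[1]
  locus_names <- names(tbl)[-1]
  long <- tidyr::pivot_longer(tbl, -1, names_to = "locus", values_to = "cell")
  names(long)[1] <- "individual"
  parse_cell <- function(cell) {
    if (is.na(cell) || cell %in% c("-", "")) return(c(NA_character_, NA_character_))
    parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed genotype cell '", cell, "'")
    parts
  }
  parsed <- t(vapply(long$cell, parse_cell, character(2), USE.NAMES = FALSE))
  calls <- tibble::tibble(
    individual = long$individual, locus = long$locus,
    a1 = parsed[, 1], a2 = parsed[, 2]
  )
  geno_matrix(calls,
              loci = tibble::tibble(locus = locus_names, kind = "SSR"),
              individuals = tbl[[id_col]])
}

read_ssr_genepop <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*$", raw)]
  if (length(raw) < 3) stop("not a GenePop file (too short): ", path)
  body <- raw[-1] # first line is the title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no 'Pop' separator found in GenePop file")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[locus_names != ""]

  blocks <- split(
    seq_along(body)[-seq_len(pop_idx[1])],
    findInterval(seq_along(body)[-seq_len(pop_idx[1])], pop_idx)
  )
  calls_list <- list()
  pop_rows <- list()
  for (b in seq_along(blocks)) {
    pop_code <- paste0("POP", b)
    for (ln in body[blocks[[b]]]) {
      if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) next
      parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(parts) < 2) stop("malformed GenePop sample line: ", ln)
      id <- trimws(parts[1])
      cells <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      if (length(cells) != length(locus_names)) {
        stop("individual ", id, ": expected ", length(locus_names),
             " genotypes, found ", length(cells))
      }
      dec <- lapply(cells, decode_genepop_cell)
      calls_list[[length(calls_list) + 1]] <- tibble::tibble(
        individual = id, locus = locus_names,
        a1 = vapply(dec, `[`, character(1), 1),
        a2 = vapply(dec, `[`, character(1), 2)
      )
      pop_rows[[length(pop_rows) + 1]] <- tibble::tibble(individual = id, population = pop_code)
    }
  }
  calls <- dplyr::bind_rows(calls_list)
  gm <- geno_matrix(calls,
                    loci = tibble::tibble(locus = locus_names, kind = "SSR"))
  attr(gm, "popmap") <- pop_map(dplyr::bind_rows(pop_rows))
  gm
}

decode_genepop_cell <- function(cell) {
  if (nchar(cell) %% 2 == 1) stop("odd-length GenePop allele coding: '", cell, "'")
  if (nchar(cell) == 4) {
    stop("2-digit GenePop coding ('", cell, "') is not supported; use 3-digit coding")
  }
  if (nchar(cell) != 6) stop("GenePop genotype '", cell, "' is not 3-digit coded")
  a <- substr(cell, 1, 3)
  b <- substr(cell, 4, 6)
  if (a == "000" || b == "000") return(c(NA_character_, NA_character_))
  c(as.character(as.integer(a)), as.character(as.integer(b)))
}

#' Write SSR genotypes
#'
#' `write_ssr_genepop()` emits standard GenePop with 3-digit coding (missing
#' as `000000`), one `Pop` block per population in map order.
#' `write_ssr_csv()` emits the CSV dialect of [read_ssr_table()].
#'
#' @param x A [geno_matrix()]; only SSR loci are written.
#' @param popmap A [pop_map] (GenePop only).
#' @param path Output path.
#' @param title Title line for the GenePop file.
#' @return `path`, invisibly.
#' @export
write_ssr_genepop <- function(x, popmap, path, title = "markerdiv SSR export") {
  ssr <- x$loci$locus[x$loci$kind == "SSR"]
  if (!length(ssr)) stop("no SSR loci to write")
  cm <- x$calls[x$calls$locus %in% ssr, ]
  enc <- function(a1, a2) {
    ifelse(is.na(a1), "000000",
           paste0(formatC(as.integer(a1), width = 3, flag = "0"),
                  formatC(as.integer(a2), width = 3, flag = "0")))
  }
  lines <- c(title, ssr)
  for (pop in population_codes(popmap)) {
    lines <- c(lines, "Pop")
    for (id in popmap$individual[popmap$population == pop]) {
      cc <- cm[cm$individual == id, ]
      cc <- cc[match(ssr, cc$locus), ]
      lines <- c(lines, paste0(id, " , ", paste(enc(cc$a1, cc$a2), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ssr_genepop
#' @export
write_ssr_csv <- function(x, path) {
  ssr <- x$loci$locus[x$loci$kind == "SSR"]
  if (!length(ssr)) stop("no SSR loci to write")
  cm <- x$calls[x$calls$locus %in% ssr, ]
  cm$cell <- ifelse(is.na(cm$a1), "-", paste0(cm$a1, "/", cm$a2))
  wide <- tidyr::pivot_wider(cm[c("individual", "locus", "cell")],
                             names_from = "locus", values_from = "cell")
  wide <- wide[match(x$individuals, wide$individual), c("individual", ssr)]
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population maps
#'
#' A population map assigns each individual to one population code and keeps
#' the populations in a stable order (with optional coordinates as metadata).
#'
#' @param assignment Data frame with columns `individual`, `population` and
#'   optionally `latitude`, `longitude`.
#' @return A tibble of class `pop_map`.
#' @export
pop_map <- function(assignment) {
  tbl <- tibble::as_tibble(assignment)
  stopifnot(all(c("individual", "population") %in% names(tbl)))
  tbl$individual <- as.character(tbl$individual)
  tbl$population <- as.character(tbl$population)
  if (anyDuplicated(tbl$individual)) {
    dup <- tbl$individual[duplicated(tbl$individual)]
    stop("individual(s) assigned more than once: ", paste(unique(dup), collapse = ", "))
  }
  for (col in c("latitude", "longitude")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_ else tbl[[col]] <- as.numeric(tbl[[col]])
  }
  class(tbl) <- c("pop_map", class(tbl))
  tbl
}

#' @rdname pop_map
#' @param popmap A `pop_map`.
#' @export
population_codes <- function(popmap) unique(popmap$population)

#' Read a population map from TSV
#'
#' Accepts either a headered file (`individual`, `population`, optional
#' `latitude`, `longitude`) or a headerless two-to-four column file in that
#' order; fields may be tab- or whitespace-separated.
#'
#' @param path Path to the TSV file.
#' @return A [pop_map].
#' @export
read_population_map <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*$", raw)]
  if (!length(raw)) stop("empty population map: ", path)
  fields <- strsplit(raw, "[\t ]+")
  has_header <- identical(tolower(fields[[1]][1]), "individual")
  if (has_header) {
    header <- tolower(fields[[1]])
    fields <- fields[-1]
  } else {
    header <- c("individual", "population", "latitude", "longitude")
  }
  if (!length(fields)) stop("population map has a header but no rows: ", path)
  ncol <- length(fields[[1]])
  mat <- do.call(rbind, lapply(fields, function(f) {
    if (length(f) != ncol) stop("ragged population map row: ", paste(f, collapse = " "))
    f
  }))
  tbl <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(tbl) <- header[seq_len(ncol)]
  pop_map(tbl)
}

#' @rdname read_population_map
#' @param popmap A [pop_map].
#' @export
write_population_map <- function(popmap, path) {
  out <- as.data.frame(popmap)[c("individual", "population", "latitude", "longitude")]
  if (all(is.na(out$latitude))) out <- out[c("individual", "population")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 12-population sampling-design map
#'
#' Loads the sampling design shipped with the package: 12 populations (two
#' native, ten introduced; codes CAM, GHN, SR, NR, CWK, SK, NPM, CPM, SPM, SS,
#' NS, SBH) of 15 individuals each, with collection-site coordinates carried
#' as metadata. Individual IDs are synthetic placeholders.
#'
#' @return A [pop_map] of 180 individuals.
#' @export
study_population_map <- function() {
  read_population_map(system.file("extdata", "populations.tsv",
                                  package = "markerdiv", mustWork = TRUE))
}

#' Write a phenogram as Newick
#'
#' @param tree An [ape::phylo] tree (e.g. from [upgma()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label) || !length(tree$tip.label)) stop("tree has no leaves")
  if (any(is.na(tree$tip.label) | tree$tip.label == "")) stop("unnamed leaf in tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around seqinr keeping sequences as named upper-case character
#' strings, the representation used by [scan_ssr_motifs()].
#'
#' @param path FASTA file path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, `[[`, character(1), 1))
  names(out) <- names(recs)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (!length(sequences)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, as.string = TRUE, nbchar = 70)
  invisible(path)
}
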