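#' Read diploid multi-locus genotypes
#'
#' Two dialects are supported. Genepop: title line, locus names (one per
#' line or comma-separated on one line), populations delimited by `Pop`
#' lines, individuals as `id , a1a2 a1a2 ...` with 2- or 3-digit allele
#' codes and `00`/`000` marking a missing allele. The Genepop format carries
#' no population names, so populations are labelled `pop1..popK` in file
#' order. Long CSV: columns `population`, `individual`, `locus`, `allele1`,
#' `allele2` with `0`/`NA` for missing.
#'
#' @param path file path.
#' @param dialect `"genepop"` or `"long_csv"`.
#' @return object of class `genotype_table`: list with `populations`,
#'   `loci`, and `data` (a long data frame `population`, `individual`,
#'   `locus`, `allele1`, `allele2`; missing alleles are `NA`).
#' @export
read_genotypes <- function(path, dialect = c("genepop", "long_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("population", "individual", "locus", "allele1", "allele2")
    if (!all(need %in% names(df)))
      stop("long CSV must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    df$allele1 <- ifelse(is.na(df$allele1) | df$allele1 == 0, NA_integer_,
                         as.integer(df$allele1))
    df$allele2 <- ifelse(is.na(df$allele2) | df$allele2 == 0, NA_integer_,
                         as.integer(df$allele2))
    return(new_genotype_table(df))
  }

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("truncated Genepop file", call. = FALSE)
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("no Pop delimiter found", call. = FALSE)
  loci <- unlist(strsplit(lines[2:(first_pop - 1)], "\\s*,\\s*"))
  loci <- trimws(loci[nzchar(trimws(loci))])

  pop_id <- cumsum(is_pop)
  rows <- list()
  for (i in seq_along(lines)) {
    if (i < first_pop || is_pop[i]) next
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2)
      stop("malformed individual line: ", lines[i], call. = FALSE)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(toks) != length(loci))
      stop("individual ", id, " has ", length(toks), " genotypes for ",
           length(loci), " loci", call. = FALSE)
    w <- nchar(toks)
    if (!all(w %in% c(4L, 6L)) || !all(grepl("^[0-9]+$", toks)))
      stop("malformed genotype token for individual ", id, call. = FALSE)
    half <- w / 2
    a1 <- as.integer(substr(toks, 1, half))
    a2 <- as.integer(substr(toks, half + 1, w))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    rows[[length(rows) + 1]] <- data.frame(
      population = paste0("pop", pop_id[i]), individual = id,
      locus = loci, allele1 = a1, allele2 = a2,
      stringsAsFactors = FALSE)
  }
  new_genotype_table(do.call(rbind, rows))
}

new_genotype_table <- function(df) {
  pops <- unique(df$population)
  if (length(pops) < 2)
    stop("need at least 2 populations for pairwise distances",
         call. = FALSE)
  structure(list(populations = pops, loci = unique(df$locus), data = df),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d populations, %d loci, %d individuals\n",
    length(x$populations), length(x$loci),
    length(unique(paste(x$data$population, x$data$individual)))))
  invisible(x)
}

#' Allele frequencies per population and locus
#'
#' Frequencies are counted over non-missing allele copies only; an
#' individual with one missing allele still contributes the other copy to
#' the count. Population-locus combinations with zero non-missing copies are
#' flagged undefined (frequency rows absent, `n = 0`).
#'
#' @param table a [read_genotypes()] result.
#' @return object of class `allele_freqs`: list with `freq` (data frame
#'   `population`, `locus`, `allele`, `freq`), `n` (data frame `population`,
#'   `locus`, `n` allele copies), `undefined` (data frame of flagged
#'   population-locus pairs).
#' @export
allele_freqs <- function(table) {
  df <- table$data
  long <- rbind(
    data.frame(population = df$population, locus = df$locus,
               allele = df$allele1),
    data.frame(population = df$population, locus = df$locus,
               allele = df$allele2))
  long <- long[!is.na(long$allele), , drop = FALSE]
  cnt <- stats::aggregate(list(count = rep(1L, nrow(long))),
                          long[c("population", "locus", "allele")], sum)
  n <- stats::aggregate(list(n = cnt$count),
                        cnt[c("population", "locus")], sum)
  cnt <- merge(cnt, n, by = c("population", "locus"))
  cnt$freq <- cnt$count / cnt$n
  all_pl <- expand.grid(population = table$populations,
                        locus = table$loci, stringsAsFactors = FALSE)
  undef <- all_pl[!paste(all_pl$population, all_pl$locus) %in%
                    paste(n$population, n$locus), , drop = FALSE]
  n <- merge(all_pl, n, by = c("population", "locus"), all.x = TRUE)
  n$n[is.na(n$n)] <- 0L
  structure(list(
    freq = cnt[order(cnt$population, cnt$locus, cnt$allele),
               c("population", "locus", "allele", "freq")],
    n = n[order(n$population, n$locus), ],
    undefined = undef), class = "allele_freqs")
}

freq_vector <- function(freqs, pop, locus, alleles) {
  sub <- freqs$freq[freqs$freq$population == pop &
                      freqs$freq$locus == locus, , drop = FALSE]
  out <- stats::setNames(numeric(length(alleles)), alleles)
  out[as.character(sub$allele)] <- sub$freq
  out
}

#' Cavalli-Sforza and Edwards chord distance
#'
#' For populations X and Y with allele frequencies `x`, `y` at each locus,
#' `Dc = 2 / (pi * L) * sum over loci of sqrt(2 * (1 - sum_a sqrt(x_a y_a)))`.
#' The `2 / (pi * L)` normalization is included (some published variants
#' omit it), bounding each pairwise value by `2 * sqrt(2) / pi`. Loci
#' undefined in either population of a pair are dropped from `L` for that
#' pair.
#'
#' @param freqs an [allele_freqs()] result.
#' @return labelled symmetric distance matrix.
#' @export
chord_distance <- function(freqs) {
  pops <- unique(freqs$n$population)
  loci <- unique(freqs$n$locus)
  D <- matrix(0, length(pops), length(pops),
              dimnames = list(pops, pops))
  defined <- function(pop, locus)
    freqs$n$n[freqs$n$population == pop & freqs$n$locus == locus] > 0
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    acc <- 0; L <- 0
    for (locus in loci) {
      if (!defined(pops[i], locus) || !defined(pops[j], locus)) next
      alleles <- unique(freqs$freq$allele[freqs$freq$locus == locus])
      x <- freq_vector(freqs, pops[i], locus, alleles)
      y <- freq_vector(freqs, pops[j], locus, alleles)
      acc <- acc + sqrt(2 * max(0, 1 - sum(sqrt(x * y))))
      L <- L + 1
    }
    if (L == 0)
      stop("no shared defined loci for populations ", pops[i], " and ",
           pops[j], call. = FALSE)
    D[i, j] <- D[j, i] <- 2 / (pi * L) * acc
  }
  D
}

#' Pairwise Weir-Cockerham FST
#'
#' The Weir & Cockerham (1984) theta estimator computed for every population
#' pair, multi-locus as the ratio of summed variance components: for each
#' allele at each locus the among-population (a), among-individual (b) and
#' within-individual (c) components are formed from sample sizes, allele
#' frequencies and observed heterozygosities, and
#' `theta = sum(a) / sum(a + b + c)` over all alleles and loci usable for
#' the pair. Per-locus sample sizes count individuals with a complete
#' genotype at that locus. Slightly negative estimates (no among-population
#' variance) are retained; clamp to zero before ordination or clustering
#' with [clamp_nonneg()].
#'
#' @param table a [read_genotypes()] result.
#' @return labelled symmetric matrix of pairwise theta.
#' @export
fst_weir_cockerham <- function(table) {
  pops <- table$populations
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    comp <- wc_components(table, pops[i], pops[j])
    if (comp[["abc"]] == 0)
      stop("no usable loci for populations ", pops[i], " and ", pops[j],
           call. = FALSE)
    D[i, j] <- D[j, i] <- comp[["a"]] / comp[["abc"]]
  }
  D
}

# summed W&C (1984) variance components over loci and alleles for one pair
wc_components <- function(table, popA, popB) {
  df <- table$data[table$data$population %in% c(popA, popB), , drop = FALSE]
  complete <- !is.na(df$allele1) & !is.na(df$allele2)
  df <- df[complete, , drop = FALSE]
  r <- 2
  sum_a <- 0; sum_abc <- 0
  for (locus in table$loci) {
    sub <- df[df$locus == locus, , drop = FALSE]
    n_i <- c(sum(sub$population == popA), sum(sub$population == popB))
    if (any(n_i == 0)) next
    alleles <- unique(c(sub$allele1, sub$allele2))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      dose <- (sub$allele1 == al) + (sub$allele2 == al)
      het <- sub$allele1 != sub$allele2 & dose == 1L
      p_i <- c(sum(dose[sub$population == popA]) / (2 * n_i[1]),
               sum(dose[sub$population == popB]) / (2 * n_i[2]))
      h_i <- c(sum(het[sub$population == popA]) / n_i[1],
               sum(het[sub$population == popB]) / n_i[2])
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
           (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  c(a = sum_a, abc = sum_abc)
}

#' Clamp a dissimilarity matrix at zero
#'
#' @param D labelled matrix (e.g. pairwise theta with slightly negative
#'   entries).
#' @return the matrix with negative entries set to 0.
#' @export
clamp_nonneg <- function(D) {
  D[D < 0] <- 0
  D
}

#' Write genotypes in Genepop format
#'
#' @param table a `genotype_table`.
#' @param path output path.
#' @param digits allele code width, 2 or 3.
#' @export
write_genepop <- function(table, path, digits = 3) {
  stopifnot(digits %in% c(2, 3))
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("synthetic genotypes", con)
  writeLines(table$loci, con)
  df <- table$data
  for (pop in table$populations) {
    writeLines("Pop", con)
    sub <- df[df$population == pop, , drop = FALSE]
    for (ind in unique(sub$individual)) {
      g <- sub[sub$individual == ind, , drop = FALSE]
      g <- g[match(table$loci, g$locus), , drop = FALSE]
      writeLines(paste0(ind, " , ",
                        paste0(fmt(g$allele1), fmt(g$allele2),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
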