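.SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96-channel order
#'
#' Substitution-class major, then 5' base (A, C, G, T), then 3' base.
#' Channel names follow the `"A[C>A]A"` convention.
#'
#' @return character vector of 96 channel names.
#' @export
spectrumChannels <- function() {
    out <- character(0)
    for (cls in .SUB_CLASSES)
        for (p5 in .BASES)
            for (p3 in .BASES)
                out <- c(out, paste0(p5, "[", cls, "]", p3))
    out
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revComp <- function(s) {
    vapply(strsplit(s, ""), function(ch)
        paste(rev(unname(.COMPLEMENT[ch])), collapse = ""), "")
}

#' Classify a substitution into its 96-channel key
#'
#' Substitutions with a purine reference (A or G) are reverse
#' complemented onto the pyrimidine strand, context included, so all 192
#' raw (strand, class, context) combinations collapse onto 96 keys.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context 3-mer centered on the reference base.
#' @return channel keys like `"G[C>A]T"`.
#' @examples
#' classifySubstitution("G", "T", "AGC")  # "G[C>A]T"
#' @export
classifySubstitution <- function(ref, alt, context) {
    n <- max(length(ref), length(alt), length(context))
    ref <- rep_len(ref, n); alt <- rep_len(alt, n)
    context <- rep_len(context, n)
    if (any(!ref %in% .BASES | !alt %in% .BASES))
        stop("ref and alt must be single A/C/G/T bases")
    if (any(ref == alt)) stop("ref and alt must differ")
    if (any(nchar(context) != 3L | substr(context, 2L, 2L) != ref))
        stop("context must be a 3-mer centered on the reference base")
    purine <- ref %in% c("A", "G")
    ref[purine] <- unname(.COMPLEMENT[ref[purine]])
    alt[purine] <- unname(.COMPLEMENT[alt[purine]])
    context[purine] <- .revComp(context[purine])
    paste0(substr(context, 1L, 1L), "[", ref, ">", alt, "]",
           substr(context, 3L, 3L))
}

#' Build a 96-channel mutation spectrum
#'
#' @param snvs data.frame with `ref`, `alt`, `context` columns.
#' @return A [MutationSpectrum-class].
#' @export
buildSpectrum <- function(snvs) {
    counts <- setNames(numeric(96L), spectrumChannels())
    if (nrow(snvs)) {
        keys <- classifySubstitution(snvs$ref, snvs$alt, snvs$context)
        tab <- table(keys)
        counts[names(tab)] <- as.numeric(tab)
    }
    new("MutationSpectrum", counts = counts)
}

#' Six-class marginal of a spectrum
#'
#' @param spectrum a [MutationSpectrum-class].
#' @return named numeric vector over C>A, C>G, C>T, T>A, T>C, T>G.
#' @export
sixClassSpectrum <- function(spectrum) {
    cls <- sub(".*\\[(.+)\\].*", "\\1", names(spectrum@counts))
    vapply(.SUB_CLASSES, function(k)
        sum(spectrum@counts[cls == k]), 0)
}

#' Fit non-negative signature exposures
#'
#' Minimizes the squared error between the normalized 96-channel
#' spectrum and a non-negative combination of catalog signatures
#' (Lawson-Hanson active-set NNLS), then zeroes exposures below the
#' reporting cutoff (default 0.06) and renormalizes the survivors to
#' sum 1.
#'
#' @param spectrum a [MutationSpectrum-class] with positive total.
#' @param catalog a [SignatureCatalog-class].
#' @param cutoff minimum reported exposure (default 0.06).
#' @return An [ExposureFit-class].
#' @export
fitExposures <- function(spectrum, catalog, cutoff = 0.06) {
    total <- sum(spectrum@counts)
    if (total <= 0) stop("cannot fit an empty spectrum")
    b <- spectrum@counts / total
    A <- t(catalog@probs)              # 96 x signatures
    fit <- pracma::lsqnonneg(A, unname(b))
    w <- fit$x
    names(w) <- rownames(catalog@probs)
    raw <- if (sum(w) > 0) w / sum(w) else w
    dropped <- raw > 0 & raw < cutoff
    w2 <- raw
    w2[dropped] <- 0
    if (sum(w2) > 0) w2 <- w2 / sum(w2)
    rss <- sum((b - as.numeric(A %*% w2))^2)
    new("ExposureFit", weights = w2, rawWeights = raw, rss = rss,
        dropped = unname(dropped) & TRUE, cutoff = cutoff)
}

#' Synthetic signature catalog
#'
#' Random sparse signatures for simulation and testing: each signature
#' concentrates its probability mass on a disjoint block of channels,
#' making mixtures well separated and recoverable.
#'
#' @param nSig number of signatures (<= 8).
#' @param seed integer RNG seed.
#' @return A [SignatureCatalog-class].
#' @export
simSignatureCatalog <- function(nSig = 4L, seed = 1L) {
    stopifnot(nSig >= 1L, nSig <= 8L)
    set.seed(seed)
    blocks <- split(seq_len(96L), rep(seq_len(nSig), length.out = 96L))
    probs <- matrix(0, nSig, 96L,
                    dimnames = list(paste0("SigSim", seq_len(nSig)),
                                    spectrumChannels()))
    for (i in seq_len(nSig)) {
        p <- numeric(96L)
        p[blocks[[i]]] <- runif(length(blocks[[i]]))
        p <- 0.98 * p / sum(p) + 0.02 / 96   # small flat floor
        probs[i, ] <- p / sum(p)
    }
    SignatureCatalog(probs)
}

#' Read a reference signature catalog from TSV
#'
#' Expects signatures in rows and the 96 channels in columns (any order;
#' columns are matched by channel name and reordered).
#'
#' @param path TSV file path.
#' @return A [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path) {
    if (!file.exists(path)) stop("catalog file not found: ", path)
    m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                              row.names = 1L, check.names = FALSE))
    miss <- setdiff(spectrumChannels(), colnames(m))
    if (length(miss))
        stop("catalog is missing channels: ", paste(head(miss, 3),
                                                    collapse = ", "), " ...")
    SignatureCatalog(m[, spectrumChannels(), drop = FALSE])
}

#' Sample SNV contexts from a signature mixture
#'
#' Draws `n` substitutions (ref, alt, context) from the channel
#' distribution implied by mixing catalog signatures with the given
#' weights; used to construct spectra with known exposures.
#'
#' @param n number of SNVs.
#' @param catalog a [SignatureCatalog-class].
#' @param weights named or positional mixture weights (sum 1).
#' @param seed integer RNG seed.
#' @return data.frame with `ref`, `alt`, `context`.
#' @export
simSnvsFromSignatures <- function(n, catalog, weights, seed = 1L) {
    set.seed(seed)
    p <- as.numeric(weights %*% catalog@probs[seq_along(weights), ,
                                              drop = FALSE])
    keys <- sample(spectrumChannels(), n, replace = TRUE, prob = p)
    ref <- sub(".*\\[(.)>(.)\\].*", "\\1", keys)
    alt <- sub(".*\\[(.)>(.)\\].*", "\\2", keys)
    data.frame(ref = ref, alt = alt,
               context = paste0(substr(keys, 1L, 1L), ref,
                                substr(keys, 7L, 7L)),
               stringsAsFactors = FALSE)
}
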