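#' Write site counts as minimal VCF 4.2
#'
#' One sample column per cell (or one bulk column), FORMAT `AD` (ref,alt)
#' and `DP`. Positions are written 1-based as in the input site table.
#'
#' @param siteCounts data.frame with `cell_id` (or `sample_id`), `chrom`,
#'   `pos`, `ref`, `alt`, `ref_reads`, `alt_reads`.
#' @param path output file.
#' @export
writeSiteVcf <- function(siteCounts, path) {
    ids <- siteCounts$cell_id
    if (all(ids == "")) ids <- siteCounts$sample_id
    samples <- unique(ids)
    key <- paste(siteCounts$chrom, siteCounts$pos, siteCounts$ref,
                 siteCounts$alt)
    sites <- siteCounts[!duplicated(key), c("chrom", "pos", "ref", "alt")]
    ukey <- key[!duplicated(key)]
    gt <- matrix("./.:0,0:0", nrow(sites), length(samples),
                 dimnames = list(ukey, samples))
    gt[cbind(match(key, ukey), match(ids, samples))] <- sprintf(
        "0/1:%d,%d:%d", round(siteCounts$ref_reads),
        round(siteCounts$alt_reads),
        round(siteCounts$ref_reads + siteCounts$alt_reads))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", samples),
                       collapse = "\t")), con)
    body <- cbind(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                  ".", ".", "GT:AD:DP", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Read a minimal AD/DP VCF back into a site-count table
#'
#' @param path VCF file written by [writeSiteVcf()] (or any VCF whose
#'   FORMAT contains `AD`).
#' @return data.frame with `cell_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ref_reads`, `alt_reads`.
#' @export
readSiteVcf <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    cols <- strsplit(hdr, "\t")[[1]]
    samples <- cols[-(1:9)]
    body <- lines[!startsWith(lines, "#")]
    out <- list()
    for (ln in body) {
        f <- strsplit(ln, "\t")[[1]]
        fmt <- strsplit(f[9], ":")[[1]]
        adIdx <- match("AD", fmt)
        for (s in seq_along(samples)) {
            ad <- strsplit(strsplit(f[9 + s], ":")[[1]][adIdx], ",")[[1]]
            out[[length(out) + 1L]] <- data.frame(
                cell_id = samples[s], chrom = f[1], pos = as.integer(f[2]),
                ref = f[4], alt = f[5],
                ref_reads = as.integer(ad[1]), alt_reads = as.integer(ad[2]),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a gene model as BED6+1
#'
#' Columns: chrom, start, end, gene_id, score (0), strand (+), exonic
#' length. Coordinates 0-based half-open as in BED.
#'
#' @param geneModel gene model data.frame.
#' @param path output file.
#' @export
writeGeneModelBed <- function(geneModel, path) {
    df <- data.frame(geneModel$chrom, geneModel$start, geneModel$end,
                     geneModel$gene_id, 0L, "+", geneModel$exonic_length)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a BED6+1 gene model
#'
#' @param path BED file with a 7th exonic-length column.
#' @return gene model data.frame.
#' @export
readGeneModelBed <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    data.frame(gene_id = df[[4]], chrom = df[[1]], start = df[[2]],
               end = df[[3]], exonic_length = df[[7]],
               stringsAsFactors = FALSE)
}

#' Write the mutation matrix as TSV with M/W/. codes
#'
#' @param mm a [MutationMatrix-class].
#' @param path output file.
#' @export
writeMutationMatrix <- function(mm, path) {
    df <- cbind(as.data.frame(rowData(mm)), as.data.frame(statusMatrix(mm)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Serialize a clone tree to Newick
#'
#' @param tree a [CloneTree-class].
#' @param path optional output file; when NULL the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to file.
#' @export
writeCloneNewick <- function(tree, path = NULL) {
    cl <- tree@clones
    kids <- function(id) cl$clone_id[!is.na(cl$parent_id) &
                                         cl$parent_id == id]
    rec <- function(id) {
        k <- kids(id)
        if (!length(k)) return(id)
        paste0("(", paste(vapply(k, rec, ""), collapse = ","), ")", id)
    }
    root <- cl$clone_id[is.na(cl$parent_id)]
    nwk <- paste0(rec(root), ";")
    if (is.null(path)) return(nwk)
    writeLines(nwk, path)
    invisible(nwk)
}
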