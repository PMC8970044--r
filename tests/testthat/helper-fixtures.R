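# Shared fixtures, built in code at test time.

PROTON <- 1.007276

n762_gp <- function() {
  glycopeptide("ELHHLQEQNVSNAFLDK", "HexNAc(5)Hex(6)Fuc(2)NeuAc(3)",
               glycosite = 762, protein = "CERU")
}

# Three small spectra for MGF round-trip tests.
toy_spectra <- function() {
  list(
    ms2_spectrum("s1", 1287.6139, 2L, 41.5,
                 data.frame(mz = c(204.0866, 366.1395, 512.1974),
                            intensity = c(100, 50, 25))),
    ms2_spectrum("s2", 1113.0453, 2L, 40.1,
                 data.frame(mz = c(138.05, 657.2349),
                            intensity = c(10.5, 7.25))),
    ms2_spectrum("s3", 900.4, 3L, 12.0,
                 data.frame(mz = 300.123456, intensity = 1e6))
  )
}

# Toy identification table: 6 rows, exactly rows 1 and 4 pass all four
# confidence thresholds (hand-enumerated):
#   row 1: all pass; row 2: byonic exactly 150 (strict >, fails);
#   row 3: delta 10 (fails); row 4: all pass; row 5: pep2d 0.05 (fails);
#   row 6: fdr2d 0.02 (fails).
toy_identifications <- function() {
  data.frame(
    sample = "pool",
    peptide = c("ELHHLQEQNVSNAFLDK", "ATFNETMDYR", "EHEGAIYPDNTTDFQR",
                "ELHHLQEQNVSNAFLDK", "ATFNETMDYR", "EHEGAIYPDNTTDFQR"),
    glycosite = c(762L, 358L, 138L, 762L, 358L, 138L),
    glycan = c("HexNAc(5)Hex(6)Fuc(2)NeuAc(3)", "HexNAc(4)Hex(5)NeuAc(2)",
               "HexNAc(5)Hex(6)NeuAc(3)", "HexNAc(5)Hex(6)NeuAc(3)",
               "HexNAc(4)Hex(5)NeuAc(2)", "HexNAc(6)Hex(7)Fuc(1)NeuAc(4)"),
    charge = c(4L, 2L, 3L, 4L, 2L, 3L),
    scan_id = paste0("scan", 1:6),
    xic_area = c(100, 200, 300, 400, 500, 600),
    byonic_score = c(300, 150, 200, 450, 180, 220),
    delta_mod_score = c(25, 30, 10, 40, 15, 12),
    pep2d = c(0.01, 0.02, 0.03, 0.001, 0.05, 0.04),
    fdr2d = c(0.005, 0.001, 0.002, 0.0001, 0.003, 0.02),
    stringsAsFactors = FALSE
  )
}

# Minimal mzML writer (64-bit little-endian, no compression), enough for the
# read-subset contract: MS level, centroid/profile flag, precursor, RT.
encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

mzml_spectrum_xml <- function(index, ms_level, mz, intensity, rt_min,
                              precursor_mz = NULL, precursor_charge = NULL,
                              profile = FALSE) {
  b_mz <- encode_doubles(mz)
  b_in <- encode_doubles(intensity)
  mode_param <- if (profile) {
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  }
  prec <- ""
  if (!is.null(precursor_mz)) {
    chg <- if (!is.null(precursor_charge)) sprintf(
      '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
      precursor_charge) else ""
    prec <- sprintf(paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
      'name="selected ion m/z" value="%.6f"/>%s</selectedIon>',
      '</selectedIonList></precursor></precursorList>'), precursor_mz, chg)
  }
  sprintf(paste0(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
    '%s',
    '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" ',
    'name="scan start time" value="%.4f" unitCvRef="UO" ',
    'unitAccession="UO:0000031" unitName="minute"/></scan></scanList>',
    '%s',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
    '<binary>%s</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    '<binary>%s</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    index, index + 1L, length(mz), ms_level, mode_param, rt_min, prec,
    nchar(b_mz), b_mz, nchar(b_in), b_in)
}

write_mini_mzml <- function(path, spectra_xml) {
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>',
    '<run id="run1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">',
            length(spectra_xml)),
    unlist(spectra_xml),
    '</spectrumList></run></mzML>'), path)
  path
}
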