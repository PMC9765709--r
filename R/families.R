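# Fixed toy consensus sequences for the seven receptor subfamilies.
#
# These are synthetic stand-ins, not real receptor sequences.  They are built
# from fixed residue blocks so that the confusion structure seen among real
# subfamilies is reproduced: Rap and NprR share a large core block (the 3HB +
# TPR core that makes the Rap model match NprR proteins), while NprR carries
# an additional HTH-like block that Rap lacks.  Block sizes are chosen so a
# Rap profile covers ~73% of an NprR protein (above the default 0.6 coverage
# gate) while an NprR profile covers only ~55% of a Rap protein (below it),
# matching the observed one-way confusion.

.blk <- list(
  RAP_N    = "EQGNHWGNRIERSPGPHWNIWYGGRTHWMKHCEGHEEKWE",
  SHARED   = paste0(
    "CNKMKFLLPDKAATGSPHCLPALYSVVEHICSGDMPCCMTSSIMKVIIKQNTRWTTFACRYRIRERYQHHW",
    "TIGKWLKSFLMHKVKCWIPIQERWQHNGCRENPMRGERGPGEMFPKGNIPNLLGKEVAAHKVCWRMVWCSV",
    "KRVLSANIEMPKIWQEQDSLYDMTIDAQTFFLHRAEMDGTSNSFICYNMCEIGEQMDHVHSMPLTYHRKFIRGFIDWQ"),
  RAP_C    = "DPAIKGYMPPHREETPIWHMARKVDANLMRRNAQPLTLQT",
  NPRR_HTH = paste0(
    "MVVMYMSVSGIREFIMGMLCPQWWWCEIQRWDGTYQNNNTDVLFHIQTWQFNMVWVLHHCQDVTGSPQCVN",
    "SGEIWNKNMFWWLIQYEKA"),
  NPRR_C   = paste0(
    "PNMQRNYSDDIWYQANTGMPCVMNYGGRPMQRYSSWGDFINIAWLIVCNRDPYIEYTVQVWYHPFPSSHLM",
    "KIENQWPSFEWKDCTRWDY"),
  RGG = paste0(
    "MCTQTHENGFVQEDIDWQNAKKASMHNTHLRHTGGRHWQLSHSRKHLWNEPALQDMKYYNATQLKNNSLCN",
    "SMMTDTWPFADLWHSQYPRHWWWWHAQLCEAGYFSCHYDSSFVKHTKRYWIVHIMQKACFWHWNTGCKGLR",
    "YCAHQLEWGIWIYQMEHFPDTYMCSFIVHRKEIDGHFLFMSTENTFTFAAWYCFLQYSVKQVNNGESMHVH",
    "QQHTVQWHPHSAAAPVWYCSARKQMRHCVNVRISYNDPCFNQKELTIGVFPTTQHGFHWWNHIGLTTCIQI",
    "PKGIDS"),
  COMR = paste0(
    "REYGRVRDEWGVGKENYHVACRSMKGDITKMFKVERKRLNSLETVACVHYYCGWETRVAEWPCMTRFQIIH",
    "NADSMLYRRIAPERPTTQPMPTFGRPTKMWPIGDKGQECEDKSTWIACQVQRIDPGPDGNNIFEKETYFMF",
    "SSVWRQMWPDWVLNEKYGIRKLEFNKWMNFKCACQIAPYLQSCITSKYIFPQCFDTCCHEMYEHLDVFVWP",
    "EFIQEVMNVVCMSPRHLWVFFSLAISEERWCHHTFGSFPFLWRSVMKCITVGQWLTICNLPEYSKCHEMIV",
    "QKLYPNVACCGSMIDCGYMSADYGHM"),
  PLCR = paste0(
    "YHTSGTERIMMHVCCGLVRQVEPQNATSCIEELHIHAYVRIAGHMCHSMSWPSAEIFAEMIMSWSFLPYSK",
    "MGLVHRWAFYGTELWPGARVAGMYCIAGCQCKCSAEVIVVGIPLRMDEVIHAFMRNVCWHGHEICQFNYFC",
    "PCGIGMDECVEKCNRPHCANHSVSQAERPWCAHHRGFCKMSKMFHIMSIIYKWLLPPTSHVWIPKLAWDWG",
    "EWVYHVHDKVVHIFCLYPHRDDFFWCLCDQPACCCQSEFMQHYPWIHHTFVQMCQACKLFSIKYCQSNYMA",
    "HWQRTSDINPIEALFNMLCWIIIEHHFVRVELPFPYMKPVWKRWPYGNFHYVMYNIKHWWQYDHYD"),
  PRGX = paste0(
    "CLGMKLWHCCKVQQQQGCFSEPHWNMQHTFKRDRMSDNLQEVLILTQSGRNMYSSDFSYFMDYRCKQAVCK",
    "EGEDTYQSEGAILSTKETPDQWYIGQWEHEHAEKFHKVHVPINQRMMDEPVGRTYQCWIIKELNAGYNLLG",
    "DERHEHMSSGACISSLYRQDASEWHKANLTYTWQPLPTHWKIPQPTMGFERYAHDMKVEEDCYHLYVRKTQ",
    "RVEYFWQSGWQYNFIFASQMACVVQPVQAPDLQIVPKMARPMCMIEMVPTPNGHVVDQCCQTHCLIWGGSS",
    "TCAQHTKNCFFREHQQSAQDSMNEFYLYNCESPVLN"),
  AIMR = paste0(
    "YWQREDYECHQKMQSYPCNDEAQQKVNVCWSIQEFQLPSMRQDDIMELLPHAQPKEQIDCRFTGMTFSRHN",
    "CCAYYPFMEEMSVQSENNIMKSIAIWCIMANPNTSKCVKCYSGLFDSVRYAPMCNYCDGYRSLRMILKPIH",
    "GIKHMNKFACWRQSVYTTRRHPIWMYFHLMSAQVDITFMRHTRTQERDLTQLVEDPWPFDSHWINTYDFIL",
    "YLGGPWFLYLDTPLHETSMKLTWWNDYVMPTHLYWQGFVNFTIFVGKISPTSKGDYNVKCATGMINSNNWT",
    "CMCCFYFHNLVPTPEDFNILIREVNYYVSGPGRGQFVHGCNWDAMYSSTAIAMVNRPYKGQLGTDQEGVYS",
    "IHNCQSICMVCMKFCVDMLTFHTGWCLETVAGFWNAPHKNYRWIYRHVLGCFIDDELKKIRYWFVFDIYFA",
    "LDTA")
)

#' Names of the seven RRNPPA subfamilies
#' @return Character vector.
#' @export
qs_families <- function() c("AimR", "ComR", "NprR", "PlcR", "PrgX", "Rap", "Rgg")

#' Toy consensus protein for one receptor subfamily
#'
#' Fixed synthetic sequences (~290-430 aa) with distinct per-family blocks and
#' a shared Rap/NprR core block that reproduces the one-way Rap-to-NprR model
#' confusion. `"MutR_decoy"` returns a heavily diverged Rgg-like sequence used
#' to plant non-QS Rgg relatives (MutR/GadR analogues) in synthetic genomes.
#'
#' @param family One of [qs_families()] or `"MutR_decoy"`.
#' @return Character scalar protein sequence.
#' @export
family_consensus <- function(family) {
  switch(family,
    Rap  = paste0(.blk$RAP_N, .blk$SHARED, .blk$RAP_C),
    NprR = paste0(.blk$NPRR_HTH, .blk$SHARED, .blk$NPRR_C),
    Rgg  = .blk$RGG,
    ComR = .blk$COMR,
    PlcR = .blk$PLCR,
    PrgX = .blk$PRGX,
    AimR = .blk$AIMR,
    MutR_decoy = with_seed(424243, mutate_protein(.blk$RGG, 0.25)),
    stop("unknown family: ", family)
  )
}

#' Synthetic seed alignment for one subfamily
#'
#' Generates `n` substitution-only variants of the family consensus; because
#' there are no indels the set is already aligned and can be fed directly to
#' [build_profile()].
#'
#' @param family Subfamily name.
#' @param n Number of sequences.
#' @param mutation_rate Per-residue substitution probability.
#' @param seed Integer seed.
#' @return Named character vector of equal-length sequences.
#' @export
family_seed_alignment <- function(family, n = 8, mutation_rate = 0.05, seed = 1L) {
  cons <- family_consensus(family)
  with_seed(child_seed(seed, paste0("aln", family)), {
    out <- vapply(seq_len(n), function(i) mutate_protein(cons, mutation_rate), "")
    names(out) <- paste0(family, "_seed_", seq_len(n))
    out
  })
}
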