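LOCUS       SYN00001               16500 bp    DNA     circular SYN 01-JAN-2020
DEFINITION  Synthetic toy mitochondrial genome for parser tests.
ACCESSION   SYN00001
FEATURES             Location/Qualifiers
     source          1..16500
                     /organism="Synthetica exempli"
     tRNA            join(16450..16500,1..20)
                     /product="tRNA-Phe"
     rRNA            21..970
                     /product="12S ribosomal RNA"
     tRNA            971..1040
                     /product="tRNA-Val"
     rRNA            1041..2600
                     /product="16S ribosomal RNA"
     tRNA            2601..2670
                     /product="tRNA-Leu"
                     /note="codon family not annotated"
     gene            2671..3630
                     /gene="ND1"
     CDS             2671..3630
                     /gene="ND1"
                     /product="NADH dehydrogenase subunit 1"
     tRNA            3631..3700
                     /product="tRNA-Ile"
     tRNA            complement(3701..3770)
                     /product="tRNA-Gln"
     tRNA            3771..3840
                     /product="tRNA-Met"
     tRNA            3841..3910
                     /product="tRNA-Met"
                     /pseudo
     CDS             complement(14149..14673)
                     /gene="ND6"
     D-loop          15600..16449
                     /note="control region"
     gene            15000..15100
                     /gene="tRNA-Thr"
ORIGIN
        1 aaaaaaaaaa
//
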