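LOCUS       SYNMITO1                2000 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  Synthetic test mitogenome fragment (generated fixture, not a
            deposited record).
ACCESSION   SYNMITO1
FEATURES             Location/Qualifiers
     source          1..2000
                     /organism="synthetic construct"
     CDS             10..500
                     /gene="COX1"
                     /product="cytochrome c oxidase subunit I"
     tRNA            complement(501..570)
                     /product="tRNA-Gln"
     rRNA            571..900
                     /product="12S ribosomal RNA"
     D-loop          901..1400
     rep_origin      1401..1430
                     /note="origin of L-strand replication"
     tRNA            1431..1500
                     /product="tRNA-Leu"
     CDS             join(1900..2000,1..60)
                     /gene="ND1"
ORIGIN
        1 tatccagccc tctattgtac tcctatctca gcgcctatgc cacttcgact gcgcggttag
       61 gagcaataag atgtgcgtgg gcgcatggga ggcgctggcc atattgtatg gaggtaatcg
      121 taaggtcgcg gttggaggtc cgccacacaa ctactctttt aaacggctag acgagtacgg
      181 acagaccact ttgcgtgact cgcggagtct agtcgatctc aggcacacaa ataaaactgt
      241 ggcctcttcc cgcggcctgt ataggtagct tacgcttcac cagacccttc cctctctgat
      301 cccagctaag attgccacag gaccgagcac ctatatgggc acgtcatcag agtaatccaa
      361 gacctgcggg gacgagaggc agcacataga acgtccgaag tcgccattac ggcgatacgc
      421 tttttagggc attgttcgcc caactggtgg aacaagctgt acatttggat tatcgactca
      481 gcttgttacc gatcactgta gccttcgaaa ggtccgccgc acgtgatggc aagccaatca
      541 ctaccgactt tccattccgc ccacaggaag ggataggttt aagcgtggac acccatagac
      601 gtgggtctca gatgcaagac aggttggcac gaacccccaa gttcctccgc ggatggagga
      661 gatgtgacag agtgaccttc gcgttactta tatactagcc aatactgtag tacgacgttc
      721 tggtgatgga tgcggtgaaa cctatacgtt ctgtaaatcg aatgcggaaa gccacacacg
      781 ggcagtgtcc gcctcaccaa ccaggcgaga ttccgttcta cgtcccttag cggagagcca
      841 acaataatat acctagtgat ccctaaagga ttcaagcgag ctcaagaaac atatatcaac
      901 gcgatatttt gcatggccaa tttatgatgg agcattcaac agcgaccgga tgtgtgacgt
      961 cttctgtagt actaacggtg ggtgcgtgca gctgtattcg aggcgatcga cggagattag
     1021 tatagattca tctctcttcc atctagattc gtatgtagtt gcaatccttg catcagaaaa
     1081 aggtaacacg aatatgccaa ttcctgtgcc tgggttgaat ctatccggga accgaagcta
     1141 tgcacgggac cagcctgcgt cggtccggaa atttttgcct tgctcggtgt gacattttga
     1201 cgttccccgt agcaaacgcc tagtgcgata tgactctcgt aggaagggac atccccatct
     1261 gaacttgcag caccgtcggt acggtaccca gaagagctta attttcgcca aagccctaac
     1321 ttttgtcacc ccattgactt caatccctaa acgcgtaatt ggccttatag tctgtgtctc
     1381 tgtatacatg ccccatgata gtatcccccc gatcatcccc ctccctgtgt gcaaattatg
     1441 tttccatcag aggcgccagt cgttggtgcg cgtgatatgc gcccaataga gcttactgaa
     1501 tgcgctctac gcacaggaca atttcggcga gtttagttct ttttgtcatc gctacgtgcc
     1561 gttattagaa atgacaggag aagtcagtta agtcactcat caagatatcg tttcaatttc
     1621 taaccaaatg gttggtccac tgtctataaa agccacccta acagttatgc agaatctcct
     1681 ttaatgactc tgctagagcc ctcctgagcg accaagatca ttctcggcca gccgttatgt
     1741 gggaccataa tccggtacga aacgtgtccc cctagggggt catcattttt acatgctctt
     1801 tttagtgatg ttatcgtacg gtactcggtg aagtgtagta taacgccttg cgtgataagg
     1861 atgacaggag tttctggcaa tacaggtagg cacagcaagc ccgccttacc tccccgtttg
     1921 acacgctcta ctcctccgga tgggtgggct gagtcctatt cgagagagga agggtttact
     1981 tgccactaag acttttcaat
//
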