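species	ctbp_context	gro_context
Ecdyonurus insignis	YPDNHPVDLSSPRPH	APMIPGSLTPPDKMNGEHPHHG
Calopteryx splendens	YTDNHPVDLSSPRPP	HHMIPGSLTPPDKMNGEHPAMH
Atelura formicaria	YPDNHPVDLSSPRPQ	PHMIPGSLTPPDKMNGEHPHHS
Machilis hrabei	YPDNHPVDLSSPRPH	PHMLPGSLTPPDKMNGEHPHHG
Catajapyx aquilonaris	STANNPVDLSSPRGS	APMIPGSLTPPDKVNGEHHSHH
Holacanthella duospinosa	VPNSNPVDLSNPSPS	SNFVPGSLSPPERMNGNDPSLL
Pollicipes pollicipes	YPDNHPVDLSSPRPE	GPLIAGSLTPPDKLGAELGLHA
Hyalella azteca	SLGHRPVDLSQAPSP	AAMLAGSLTPPDKLNSDPQQQQ
Eurytemora affinis	SETSAPVDLSAPRPN	YGMLPGSLTPPDKLNGDHCSPG
Triops cancriformis	HPEARPVDLSSSRLL	YHSSSLTLTPPDKVNVDGSNSQ
Argulus siamensis	YPENNPVDLSNSRTG	SPMIPGSLTPPDKMNGEHHPGH
Strigamia maritima	FADNHPVDLSNSHRG	SHMIAGSLTPPDKVNGEHGHQL
Sigmoria latior munda	TNENHPVDLSSSHRS	SHMIPGSLTPPDKGNAEHSHSH
Metaseiulus occidentalis	GADRKPLDMSAAHRS	
Ixodes scapularis	QAAGAPVDMSSHPAR	
Parasteatoda tepidariorum 1	VIDSHPVDLSSPKPS	
Parasteatoda tepidariorum 2	RYEGRPVDLSSPRPN	
Limulus polyphemus 1	PYDGHPVDLSNQRPD	
Limulus polyphemus 2	TYESHPVDLSNQRPD	
Centruroides sculpturatus	GYESSPVDLSSHRSV	MQLISGSMTSHDKVNGDQHSLG
Euperipatoides kanangrensis	NSYDNPVDLSSHRSS	QQILPGSLGPSDKVNGDLVSLA
Naineris dendritica	DPNGHPVDLSHSRHI	PHMIHGSLTPPDRVNGEPGSGL
Platynereis dumerilii	MASENPVDLSSRHVG	GNHFPGTLTPPDKLNGDHNAHH
Nephasoma pellucidum	AGYETPVDLSSPRPC	SHLIPGSLTPPDKINGEGITTS
Owenia sp.	QPYENPVDLSRRHIK	AHLIPGSLTPPDKINGDMVTMA
Octopus bimaculoides	NGFDNPMDLSNGKVV	HLMPAGSLTPPDKISGDSISMA
Crassostrea gigas	GGYENPMDLSSNKPG	SHIVAGSLTPPEKINGDPGAMA
Lottia gigantea	AGVENPVDLSNGRIS	SHLFTGSLTPPEKPNGDLVPMS
Notospermus geniculatus	VQYDNPIDLSNRLEG	NHMIPGSLTPPDKVNGDMVPLP
Malacobdella grossa	LHYDNPLDLTNRLDE	GSGIAGSMTPPDGGKGNDLDLQ
Lingula anatina	GGYENPMDLSRRTEM	AHMIPGNLTPPDKVNGEMVPMA
Phoronis australis	QHDNRPMDLSSRGQH	SHLIAGSLTPPDKVNGDVVSMA
Procotyla fluviatilis	ETLFEPLDLRSPIGV	
Brachionus koreanus	AKDETPIDLSSKKSK	
Xenoturbella bocki	KRYSAPLNLTVHDKC	DVRVLGRLTPPDKQHVNNDVGA
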