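>Ecdyonurus_insignis species=Ecdyonurus_insignis
YPDNHPVDLSSPRPH
>Calopteryx_splendens species=Calopteryx_splendens
YTDNHPVDLSSPRPP
>Atelura_formicaria species=Atelura_formicaria
YPDNHPVDLSSPRPQ
>Machilis_hrabei species=Machilis_hrabei
YPDNHPVDLSSPRPH
>Catajapyx_aquilonaris species=Catajapyx_aquilonaris
STANNPVDLSSPRGS
>Holacanthella_duospinosa species=Holacanthella_duospinosa
VPNSNPVDLSNPSPS
>Pollicipes_pollicipes species=Pollicipes_pollicipes
YPDNHPVDLSSPRPE
>Hyalella_azteca species=Hyalella_azteca
SLGHRPVDLSQAPSP
>Eurytemora_affinis species=Eurytemora_affinis
SETSAPVDLSAPRPN
>Triops_cancriformis species=Triops_cancriformis
HPEARPVDLSSSRLL
>Argulus_siamensis species=Argulus_siamensis
YPENNPVDLSNSRTG
>Strigamia_maritima species=Strigamia_maritima
FADNHPVDLSNSHRG
>Sigmoria_latior_munda species=Sigmoria_latior_munda
TNENHPVDLSSSHRS
>Metaseiulus_occidentalis species=Metaseiulus_occidentalis
GADRKPLDMSAAHRS
>Ixodes_scapularis species=Ixodes_scapularis
QAAGAPVDMSSHPAR
>Parasteatoda_tepidariorum_1 species=Parasteatoda_tepidariorum_1
VIDSHPVDLSSPKPS
>Parasteatoda_tepidariorum_2 species=Parasteatoda_tepidariorum_2
RYEGRPVDLSSPRPN
>Limulus_polyphemus_1 species=Limulus_polyphemus_1
PYDGHPVDLSNQRPD
>Limulus_polyphemus_2 species=Limulus_polyphemus_2
TYESHPVDLSNQRPD
>Centruroides_sculpturatus species=Centruroides_sculpturatus
GYESSPVDLSSHRSV
>Euperipatoides_kanangrensis species=Euperipatoides_kanangrensis
NSYDNPVDLSSHRSS
>Naineris_dendritica species=Naineris_dendritica
DPNGHPVDLSHSRHI
>Platynereis_dumerilii species=Platynereis_dumerilii
MASENPVDLSSRHVG
>Nephasoma_pellucidum species=Nephasoma_pellucidum
AGYETPVDLSSPRPC
>Owenia_sp species=Owenia_sp.
QPYENPVDLSRRHIK
>Octopus_bimaculoides species=Octopus_bimaculoides
NGFDNPMDLSNGKVV
>Crassostrea_gigas species=Crassostrea_gigas
GGYENPMDLSSNKPG
>Lottia_gigantea species=Lottia_gigantea
AGVENPVDLSNGRIS
>Notospermus_geniculatus species=Notospermus_geniculatus
VQYDNPIDLSNRLEG
>Malacobdella_grossa species=Malacobdella_grossa
LHYDNPLDLTNRLDE
>Lingula_anatina species=Lingula_anatina
GGYENPMDLSRRTEM
>Phoronis_australis species=Phoronis_australis
QHDNRPMDLSSRGQH
>Procotyla_fluviatilis species=Procotyla_fluviatilis
ETLFEPLDLRSPIGV
>Brachionus_koreanus species=Brachionus_koreanus
AKDETPIDLSSKKSK
>Xenoturbella_bocki species=Xenoturbella_bocki
KRYSAPLNLTVHDKC
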