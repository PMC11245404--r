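seq,mw,pi,instability,gravy
PILTQACWKRWQACSDGYVNDPMDPCIATKRTVEHYVGKNVQTKFGCPCSWVKKATMHMKMGDFNYK,7744.9776,9.1239,58.2537,-0.568657
RKMSCVLKDCLGKPQCCKDYMNACHTCDPPPWQFLMWCWNNNAEKDSYVGNVYTHPEDEKTWE,7489.4656,5.5632,58.946,-0.9
SGNWCPDSCGMCDNWDTIAHVCTMGQQVMIQQYWYWWIGERWYYTTARQVGWFEDSASNN,7177.8515,4.228,38.6783,-0.596667
PTRHTDWQQTQCTNPGIWFCSCYQRWTG,3401.7256,8.3128,41.2357,-1.096429
YEFWFTNTPYKFIETIMQMIMAPQELGQHKFSWSHTYEMEEYQVQANMTYRTNT,6722.5038,5.0578,22.0019,-0.746296
YWHVGHFDEQEVIPQHYCGEEN,2716.848,4.5478,68.95,-1.15
LPLWPIKSTHVWAMGQIIHSSSNEYYRHAYYCFYHKGWEVYNWLTDHMTLFLAGYQSLVWVDSEGWRHEYVDKDELRQWDDWGCWWVRCFYWYSAWCEIFYSTM,13056.5429,5.5493,42.3359,-0.423077
VDCSCARVFTSKTIDIEMMPMYPKEDDSAGKEYGTVWDYPYDQRQWIKFWIMDVQSEIWTDQEDMMLFFCNKWKWPWVRHHQFGWPALVEMQQTVSK,11882.4662,4.8233,47.1454,-0.58866
PRTRIQYRDINYEKHGGQQYFTGLTMHQWYQNWYFYPKIQDCFICENYKWLYFRRLDQHLMHDHRPPNAWQHTLCEIGQLKLITFSIPLWCGNVTHNQEGVYLPTLHSLQHDPTCCM,14347.2016,8.0493,40.4215,-0.694017
EGTPHRLIIDVWSHEHRIPL,2405.7118,6.2811,0.045,-0.49
SQDEIYETAWWDQTVWIWSWTKPTKCCGIKMKDNCPSQFHFLMRRVQCPYECYNEGRVRINSSTAVPHMKPECNKSGRKESCQCYKNDWMHFCFCDAKCEQQVHFGFSGTRTKL,13607.4255,8.4939,47.1386,-0.796491
SVLMYTNTMNGNETMTWWESEDKQWFQLYASRAAAFTVWNTGTMISVRHPEAEQDHYVVAGPKFKEQSLKSDDIDNPSEGGSNDINPMWRVLE,10717.7017,4.618,36.3914,-0.736559
GSQAACQYCQSKFIVGVTWLSYPMWGHAGPNLHSLSMNNMWSHCYPSIADWRTRVVKNCSYFTYLWNEKYKMPPV,8768.0112,9.0282,39.096,-0.32
YYHQLYKFNTAWRELLTVYSIDDLQLFNCFITYNVYVDRITVWFCILTIWPHPCTDFNCCQIFA,7884.0275,5.3008,14.8031,0.304688
RWLMHVGYGCHNASMDFSRCWPKSLRVFASILESCCSCNKETVRNFSDVEVIHGDPMWIVGSKLINEAKCPSCQPGW,8750.0429,7.7577,61.9766,-0.142857
QELFWPLFCHDEYFIPDLDEGDDQCDFNMFEWSVHVNDCMKMSSQHRFYYWGLHTDMCQRDRNLVHCLFWEAECTHVDMMVFAEQNCCSIWYKP,11589.9699,4.4809,39.5639,-0.438298
HSRMQQCFRGEEAIYMMKSDRWPENAGPNLIDFEDTCMPK,4763.3739,5.0489,65.105,-0.9625
KPAMHENKKSYQMADESFHIWAR,2805.1537,8.4457,72.4783,-1.26087
ESRQSFFIFDNTDYIGFYEESFAHLAYSVCYWHDSQLIHCGVVAYITMYVKMLCGKIRSQPKNLFLHHVIDVYEPLVEVRSKSNKRHNPAWAGWLPDFILWSSPYLWANQH,13202.9029,6.7194,67.7343,-0.173874
KCSWQDQIEFSPFKYCVPCGNCEWVMRRCKHWGVICHYTAVLCIVEQQQMFTFVLTSAQLCSCFFMEDWYFVSIVPQHLTMPPLRRASWCHASLVMKVPSRYGFAPYRTQW,13231.4414,8.5801,57.5793,0.059459
EVWPRQEMLQFIEHFERLNEINENCFAGCDRCIKIYRVFSVYDLAITDKLRRMKKIKM,7169.3834,8.5956,38.7241,-0.394828
VALHQSAFFINRYCRARKPIEKIRPERQWIIEGRMPVLHDIYAMNMGHIGESMCWHHELMNPTFTTGKKRSH,8603.9764,9.778,68.6208,-0.559722
LVSDKMDWCMKASECIGIHRQKSVWNNCHRHEIDYDHITNTAPGDPICECEAHNIVAYQKMRVVKMTTPGMGDELYKITITPETELKKWQVQNPFNHMN,11545.1292,6.301,56.5596,-0.655556
LGKHNVPYNGCHCMINTGSNWSRIF,2849.2324,8.9048,40.212,-0.376
PSCITVKFFK,1169.4354,9.376,42.95,0.59
YEWVGKKAMRPSNCFYTWVHIWGNQWRSEISARSRSGRRGRCKWDGTWGQPCWKAECWDFKLMPAGWRECNFWMCGKQGWMWLKSKEMKYDSEFVMGINVGSEEHETFTIMCQD,13766.6378,8.7296,60.0352,-0.786842
DWTCLPHWGTDG,1387.4753,4.1967,10.625,-0.791667
TPPFKGQLIALRQHRIYCIS,2341.7754,10.0521,36.26,-0.065
YHCNQFIDGMVTWANQGCVHITYYGAMFIKEAYYKLMVLSENKM,5213.0394,6.9008,22.0068,0.009091
AKQPYGSLWRGINLMNPRRFAWVAEETEYLWITYSNMKCCKQLHWWSTRATMSAKCQVLQRNHNPCHRSKPQCKMDSPHQPFSAMHMFNDSIIGWNPGRNHTKY,12398.1313,9.7181,65.7712,-0.858654
ERVWPPTLTNSMSAMNWRRWEYHWK,3262.6813,9.98,74.328,-1.284
SMYYVKFGLDMAYKAEEDTTGSLHIWVSLNSPHDCYM,4303.8217,4.7966,63.0135,-0.254054
PGSDDNRQIYYNPPEVTKENHPRQFHEKETSPAGPEAYPDHTKKLGEQCICHGAFW,6451.953,5.704,35.7929,-1.396429
YLRIAYVHPWKWPPPAILHNTHNFLAKFASCPIIYPSTALTDTMFCITNCFKSFCKIRGAWITRFCQSPHPAKFEKLSTECSDRFKRENTMPR,10926.6889,9.5046,43.6312,-0.273118
AYCNMKQFWWHIVWYFTKFSDRGYSAAMTLWDHAYWAFTKVWCAHNYWLYNVWTFSMYIHEEPDHRAWIIYFVTAPGFVSCQQNPWPHDEVCGEHNLE,12108.5155,5.9193,29.3224,-0.326531
AQQRVWNDRLLNETARKPGTICIQMTMWYAYYGIFYEDWKECLDPDYMAPIGIAWRYMHCMLCFSVTPLMYSIVWINACWTKDKHESLASIGCIIYSSQKHRRRPRDKKGEQMK,13681.8431,8.9343,57.9036,-0.442982
NEGEGHIDYRYPKWDQWLDMTEPDMEGMTLGIQALCAMQDATKRVGNTKWANEKWYICYERPWAMNFNNPQHDDKPFGCEPCDVWRNGQLHGWRSSPPDEHGQCWLSQWSDKHDTT,13747.0223,4.9157,28.1034,-1.181034
PEKLRPEGYCEHSGCLCSSRR,2407.708,8.3006,87.5333,-1.128571
SGHRQGSDSETESSSGDKKQYRFIWPWSGGPVNEDPQYIGIVENYFDYLDWDGFHMTSPAPWWHEDMWDIASMRCAKCNLQEYCWW,10244.0782,4.4897,52.7,-0.934884
RPHLQPGQYERIWGQWIEEYDQIHTKQWYPNLPCIHVGARDKRQNASACCRSENQFKCCNQGSPSFWTTLHIPAMANFWDHVGCSWYVMHEKFYEYVPKGVQSDYPPNLENCLALMIQK,14120.8602,7.1331,59.4076,-0.716807
IAIGRHVWVTKKKRNDLYQHWSETPCPDRSMRGGYARSCCGRRNVNFISTNYMVWVVAICCVHDHYWRHEINPGYNRDCRCTNTEAEKSDDIAPGMKFGQMQ,11968.4896,8.9352,45.2422,-0.758824
WTYYGCSMHYWMGQILAPKKHDKHNMITFSIHLIGKETKQRMWRLSALMWRAPRNSWLYIEEGYTLYQMLNDVVCWW,9544.0804,9.2663,50.9779,-0.41039
KNHQHMTHVAKDGDQQH,2011.1422,7.0971,19.0471,-2.047059
RMMAVDDWPMSWMDTRKHVSHRCQADDAEVWFCQLWICQYAFQEIINCKGDSAVHPLEVSYHMDLVRMWGCSEAPSKHSKLERIQSGQQDAIMRKGLNDQQRFMQWGCSIFVSYGGVGVF,13993.8912,6.1919,27.0933,-0.361667
GAIASFLPPMQTTDQANCENAMHGVHVRLKFYNYFFCFRCRHMNKDLTRCNPDEPCDSQWGWADKIYNWPYLCFIP,9025.2379,6.9709,27.412,-0.448684
MEMMPAIMVGCHKAQQHNMEGCPSQDNEWDNAQDEWQTGHLHYQTNCQALINCSRCMDVSWIGQESSWTQDAPMGQSARFQASAHNAKD,10085.0381,4.8938,55.0101,-0.852809
QHTNDWHGEYVTNMKYYHKYPQMFYFNCSELGIEMANATVFSWTVGYYRVVHPPAMNHVFIIPNSVD,7990.9305,6.1729,27.3972,-0.359701
FSIGNLCRATYECSQGHYELRPIHLTKESNDGWHECGFFDCYSYHCVDNIRKGGASMAMNLGTDNFEEYGEHQQLQGKHLKCMNHYMREPLPICAMLCSRFRDHYHT,12525.9888,6.2955,59.1822,-0.697196
FCVAWPREKLCLSDFPSTFDDVWQQGSEYVSPAKIQVPMLMEAEYILWRYNRKSMN,6705.6506,5.1001,42.7071,-0.353571
WTTYIWGILRHSLCVFTFHYTEEPSDLFCPNDM,4023.5253,4.7241,62.3576,-0.027273
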