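>terminase_large_subunit synthetic_marker_seed
QNVNRSSRLETLRGAYFMNCCGYQDDSHFIPDPDPLNRQQMYECSMFPEYLDKDGQKTMR
RVNYWPQLKWHVVNRSKRPKHFQRKFLLRLDLLKGFLDCDTNPEWSLLHHVKCKRSLSVS
KMKETADGVMRRWQVWLKNNLFELFQKVSDWDQNERMYAYFNFKMTRKQLMAQPDHGYWV
DMISQLYGPDLWTHFPFPCSHLVPRTDFEVYHPDTWAQKCPLDQSIKCAFRRLNGKKSRA
KKEMFFSGVQSCPVYAWAWEHAMTKWYYVHLKAQNPFEVKVQFCGYKHVILASGMPCWLW
MQGARHTKPMIEERWAQVWSFHNCNAAIGKGHSYNQRMAMDANCMDQKRKMTMHIPCVHR
FKLEHAKRSRNKGHPRRRPHCNHAMKMQSIQIRYWRAGSSSGVKLLEHIEPCLSETRFYG
SLIYIFPWWKNQDEPYQHWGVVAMKLLDQFPEVALYMKVQMRESAMQCFIKLGYPLYVCR
>portal_protein synthetic_marker_seed
QITVPHAIRRDISYANNTVHEEKHISVFRQTQCYVYLTINAEYTNEVTQHVCQPQHAPYK
TTIYKAALITWPYTCVEMIMQSSPHRSVDQLWRATHFVKVTMPNDRTPHCMVHVSHKTAR
SLDQRCPHLHRALEFRRPSEPGRCTDNKFINIERVYLALYTDLAAGEAPCTVQSVKWESY
KMFVNNLHKHFIWKHRRMTHHYLEYAATYFLLGNMKFMKELWYFCSKPHLCAFRPHFQIV
MYTVDTFPQHDCDRRLTDMGWLRQHTENMLAWGTFNPLEAGKQWVIMVYKSKYPTIVWII
ERYYISGCKVPSQQTDVVEQDWFYWLWRISMKLFDNRTFCNWLVNEHWELTVERPCHDNP
DWEENFKLRLLEDTMHKLWGRHRGTAVYTCGLQQHDMHQMGMEGDMTGFQLPTGRPYLDE
>clp_protease synthetic_marker_seed
SVHAKDTWKKLLIPQNKFMSAARRLCPQIWHDVAEATTALANISMCSRWGDQPESWVCYP
APCIMIDYEHYGYQRCDQFEIWTVFKCCNSTREPHIPWERFLSHHEELKYHTLDVKKIED
AESIYERDSPCKPQLFTVWVSCGWVGIIFSLHGYIEPLWESAIWCGWQVLDVQYGEAKWY
LDCFGANQNEDYCALVCGAKMCIRNDSRFAMRHGAEMLQDNFCPHIEAFH
>major_capsid_protein synthetic_marker_seed
MHLSVDKVCVYCNNYQTVVCGFRWACMRDEDIPSTKIFQHYCKYEYSIEIERHITFEWQA
QYKATYFNQPMDIMCKYIPDIGKIQPGTLHSPMEWIYENRLHCLMILFRRQMHVRAHPIA
PPTIRTQADLMDHHNWRKCRGWMMPGEKPRMYGHPWPKSDVISIIKDTSYRRFVGLAKKL
WIRVRLELSGDTDYTMYWHLRNRFVYALCGFVPGCDGEQKPTMWWLTHQTIPKVNLRTMA
CCHAQNEWLSELIMHSLEHRGITDVSRRWVCTSIPLGCCYTLELHYPNHCYEKHHTLHAE
KHAKAFLICVMQAIYGQVYYIGHNGCQCSNARHKCYTKSD
>dna_polymerase_I synthetic_marker_seed
SMTIDLFRWSVAYVWEVEWANMLVIPFTKEPEAACHCTFNDEALDSIQRGCPAPTSCNAF
SDFYIPDTDANMSFGAQHRMLDWGVIVELCGPIYATYGYNCMIAWSQSQYEMMGIQCEHN
CICNFIFHFYIVHNGEIHQWGYNPCIFFSILIEVPRLKFEMDMFKYLEATGNDYPTMNSM
FYEQQPKSCRLCPNWCSHHHSFWNLGSHIYKDRTNLMDMRQDYACWIESWECLMQPHQDV
EMVRCRSINYLMKITYKNRRPHYADASCQCHLAKSQTDWQPTYFYFDASNAIARAINIWM
WLPIKMHNYEQKKHTMHCRDKNKMCSGSAPISMICVGMPDTCLKLRFPLDPCGYTAQYKI
KRSLDIIRQGCGWNTKLWMQFYVCPMYWFDENQEGHMNRNSHIMCKEYYRFMYKTFRPIR
QRRHWRMLVFHLEPCVDGNPEEEPATPHPAVTQQQVNAAMRIIIWQEEYISQNYRQGWPW
NHMFKKAGDSMCFTSYLLTFGDCKPGAWISRPWCVMSDPYRNIVFFFWWFIWRYMAACKL
SMNVNYDHVEHGNCGQEAIT
>snf2_helicase synthetic_marker_seed
PMMVLMTFVIFYRRPIQFIGYTEGFWKLVYWEDQVDRFPGQCDMMDNMGKTRRIAYELGH
EYWKPWQISEPKKQWHIQPKPNMEIANPHCWIALHQTCPLRRRGLDAQLNIFERFIKHEH
FLNCPFHSSEPAPIRWCMACKSAPWMQMNIAWKKIREKVFMPIDWKGFAFGGDDNYFPGS
LQFSHLWLCETHNWPNQQTMEGHFRWQRSDPFYRFMPMFLVETYETEWEANLPLRCHAMS
NECYKSYATKLTFFCLNYTQNFNQSFHLSDHHQGRLFLKADMGNPIRTEIRTNHWCGAFY
LKMPDAECLGEAPKQRIASVSITFLPSDYLNIYWHSNRVLFPFFLECKPCRWCNSVHTYK
WHRNANQWDHSKVDHPMGDEFQVYKSAWEAFPVTMSRIEMKITCAYKDLVWCFCMGCTQY
NVQVHTAPIINNTREHKYNQEQFHYVFNWRQRHVKFQICDTFSKMTICKATEVMPAPEQF
MDPVQTTLRIMPMDDKCENMGHWHPRYVEP
>vrr_nuc_nuclease synthetic_marker_seed
TIEHFQGSPSTEACNNKWHDTHFPDGLVRVRHFRCHMKEGVVKGEISTKLRKKRRDRSMV
AWAHFMHLGCWAPWGSPNLCMNNYGKNEHSATRCTSGQERKIVTHTDGQCRPMHIYLNVM
LKMEWFCDVWVMHTCMWMLWIEETGQAQETANVHITFFWGTTQLHHWANAYMQIMGFTKT
PWCQYGGVQVHYQNKFRQEFHTKRSRFNAVKAETVHAVSYACFSFNYEMSSFVISYSFAK
LWEDSYVEVDAWGMRLNCSI
>duf2800_protein synthetic_marker_seed
CSCQVTVECSDMYFSYQYAIAIQSATDVQQAHKMDNWWARVKTNMTEEKLFLNTCLLNVI
YLGLFTSPMMWYTRLQSHYSVATMPVGNLEKVHTMEMCLCHHYCTSFARFKECNHYLEKR
YLRWTSPKMMQCQEEWNAYHNQGCHTMHQKSAASGWITEYSQFRKKSPKLIAIFEETYNQ
ANPVSHARNLMSIVSTPPRCQEDCVFIWIFGSDLGCWANWMEWMERRPWICTSNGDTEMV
EDTHNRYKERQIHLRGKNHAPQCGDKCNMHKESPKCPVRAGDAQEGCNHDTACCGKPTSA
>duf2815_protein synthetic_marker_seed
ARGSAMYCIHFSRRPIYYMHMRHSPAYWGWTDWQYMKWKIYHDFQTEIVDHYPIQQCCIW
QDQWMGRLPRCHVHYACVSEGWGYGFCEMNYTYRDNSLNNLIPRSSYWCADEDRCILDVK
KSVKCTEGPFFSQQRHSMSRNNWLLVPDQPYLEQWLKAVHWGNVIFYRISLHPKAPGFYF
VSNGHVWEEHNYDFHGNESVFDFEPSLPNS
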