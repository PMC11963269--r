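# Synthetic domain models: consensus peptides for the packaged toy
# position-specific scoring profiles (log2-odds, p_match = 0.7) and score
# thresholds calibrated on 500 random background proteins of 500 aa
# (calibrate_profile_threshold, fpr = 0, rng_seed = 99). Stand-ins for
# real Pfam/CDD domain models; users can supply their own table.
name	threshold	consensus
GAG	-256.1	HTYQKGGPNCRTFNNTNECPQMKKQFECPQRQRKDCCHESYECQQSQTELNTGCIDKIPECGMNSVRMFHFRGWTMENAQTCRLKCCNMTFKPATFAYPVHYQYWYPCMCMRKTDGVYLVVLKPFGGIHDFQGMQAQEYCVYQHMAHNAMHVMSIEQIMMGNWGWWNDIQDMNEMYMCEVVLELGQCMASGHCIAIEWAALAQGSRRGEEFKVNYSWEDESVICMAKRWTTSIMMCNDERMHDAGTSIHG
AP	-61.14	SDRCGCACVFPLGAEWVDHKAPNQQHEQYMKGADPRRMKIVHWGTPQEAGSDYLRRLDLTVDGCACHWKEIMAINYLHIYYGFIMDQRMK
RH	-105.78	WEMYHELQYMGQIVEDILHYREDFLFLRAPHNVCGSVRIETSEFEDGTDVLKSHSDMACVWYMDIKKMAVYAVLSASYKIATTAGKRMSWICEKMWAFYYAIYECAHNRRCAWMTTTSPICNACLYNQTK
INT	-267.48	HETYPFCMLMRDFITTKMMDKWSRIMPDTTAYPFWIKGHEYSQICTMHDCLYVHINPTKHGASWYPEYHLEAWDEFYMTMWLSMNRHHMQNMHEDKVFEWGPKFGWKATQAIEGTPHPVTPHGYSCGHWWMAAVFEARRNIHEINEEKKIWKCHCVHMMEIYSKICEDQEAIQVYRSWNKRHARWWKAADIQWSTDECFHVSPLSENHDVLALTGGKFRARIFTQQGAWESEFNYKTYFLKKRHDPVLIPYPTNSVAWWPVMVIYRPGLF
TRP28	-33.13	PIIQFYDDSMHMCCNWNYFTYWMSILLQLEEIPGNMMKKWMIRMAAEYIYLANGWGKVSP
Smc	-38.82	LDRDGLHSAHGDECNRHPLLFELQSDQACGVAKQILSGEGEAAETMTVWPIANSPPKPHKMMEWVDSPIH
DNAtopo2	-55.45	ICAFHWSCTNEEKTFCRKAIYKSLGNPRPAPAYTIWGRPARIHNQYCCENDEKHEDEVHGDFAQDPVIMPEGVAELTTMG
polIII	-38.82	KPACIYHSKGIWDCAELQAFSKCDHMIAVQLIALFYPENHLRCQEKMITKAHQFPKVISQAAGREVGGPK
Mis12	-27.66	HYDVWGVLGFEHSSPEFCVAEWSHYMSQHVQTWFKTHFYCSPDTKWLPLCEFWYNWFDKD
MitoticCheckpoint	-27.66	PEGIVGEEYGFSDHGPEIWYFKHDIDFAELRIACNTWHLEYEYGPIANQTAWEYIPCGQW
TolA	-38.82	HRMSNGYPPVSAGSGHMIARQKFNQDHAHDCQIKCMMQELIPVQNLDSHNWTYKRFFMFRGGSSVFNYQW
RecomInh	-33.35	KQCQSRWPLVFDPPYQIHLWTQASTPHQMDCCGRQQLCNVADIRAQVGHRAKCEEFMGYHTNVEELLGWR
RT	-143.06	CNQGHQGNCMQNNWGMNVKDPLHSLDCVPERQNWSGNYFWRSQWNIFAFESTSNPTCPGTRSHCGTRCLGTIQKMDSSCQSVWREGLFKILVVINGQWVIYDECSKGQTGISMRFHDNEAYTPDTRYAQYACSVNGYQGSKWLQSHFNGLWHHYNTAQT
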