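organism	protein_name	sequence	reported_mh_avg
Bacteroides acidifaciens	50S ribosomal protein L36	MKVRASLKKRTPECKIVRRNGRLYVINKKNPKYKQRQG*	4587.5
Bacteroides acidifaciens	50S ribosomal protein L30	MSTIKIKQVKSRIGAPADQKRTLDALGLRKLNRVVEHESTPSILGMVDKVKHLVAIVK*	6288.5
Bacteroides acidifaciens	50S ribosomal protein L34	MKRTFQPSNRKRKNKHGFRERMASANGRRVLAARRAKGRKKLTVSDEYNGQKW*	6304.3
Bacteroides acidifaciens	50S ribosomal protein L35	MPKMKTNSGSKKRFTLTGTGKIKRKHAFHSHILTKKSKKRKRNLCYSTTVDATNVSQVKELLAMK*	7289.7
Bacteroides acidifaciens	50S ribosomal protein L29	MKIAEIKEMTTSDLVERVEAETANYDQMVINHSISPLENPAQIKQLRRTIARMKTELRQRELNNK*	7626.8
Bacteroides acidifaciens	50S ribosomal protein L27	MAHKKGVGSSKNGRESQSKRLGVKIFGGEACKAGNIIVRQRGTEFHPGENMGMGKDHTLFALVDGTVNFKVGKGDRRYVSVVPATEA*	9172.5
Bacteroides acidifaciens	30S ribosomal protein S19	MSRSLKKGPYINVKLEKRILAMNESGKKVVVKTWARASMISPDFVGHTVAVHNGNKFIPVYVTENMVGHKLGEFAPTRTFRGHAGNKKK*	9806.5
Bacteroides acidifaciens	30S ribosomal protein S17	MEARNLRKERTGVVLSNKMDKTITVAAKFKEKHPIYGKFVSKTKKYHAHDEKNECNIGDTVSIMETRPLSKTKRWRLVEIIERAK*	9959.7
Bacteroides acidifaciens	30S ribosomal protein S18	MAQQVQSEIRYLTPPSVDVKKKKYCRFKKSGIKYIDYKDPEFLKKFLNEQGKILPRRITGTSLKFQRRIAQAVKRARHLALLPYVTDMMK*	10545.6
Bacteroides acidifaciens	30S ribosomal protein S10	MSQKIRIKLKSYDHNLVDKSAEKIVRTVKATGAIVSGPIPLPTHKRIFTVNRSTFVNKKSREQFELSSYKRLIDIYSSTAKTVDALMKLELPSGVEVEIKV*	11288.2
Bacteroides acidifaciens	50S ribosomal protein L24	MSKLHIKKGDTVYVNAGEDKGKTGRVLKVLVKEGRAFVEGINMVSKSTKPNAKNPQGGIVKQEASIHISNLNPVDPKTGKATRIGRKVSSLEGKRTVVRYSKKSGEEIK*	11698.6
Bacteroides acidifaciens	50S ribosomal protein L7/L12	MADLKAFAEQLVNLTVKEVNELATILKDEYGIEPAAAAVAVAAGPAAGAAAVEEKTSFDVVLKSAGSAKLQVVKAVKEACGLGLKEAKDLVDGAPSTVKEGLAKDEAESLKKTLEEAGAEVELK*	12535.3
Lactococcus sp002492185	50S ribosomal protein L33	MRVNITLEHKESGERLYLTQKNKRNNPDRLELKKYSPKLRKHVIFKEVK*	6008.1
Lactococcus sp002492185	50S ribosomal protein L30	MAQIKITLVKSPIGRIPAQRKTVVALGLGKLGSSVVKEDNAALRGMANSISHLVTIEEVK*	6208.4
Lactococcus sp002492185	50S ribosomal protein L32	MAVPARRTSKSKKNKRRTHYKMTAPTVTFDETTGDYRHSHRVSLKGYYKGRQVRDAK*	6568.5
Lactococcus sp002492185	50S ribosomal protein L28	MSKECYFTGRKTVSSNNRSHAMNQTKRVVKPNLQKVQILENGELKTVWASAKALKKLPAGVERV*	7070.2
Lactococcus sp002492185	50S ribosomal protein L29	MKLNETKSLLKDLRALSIDELATREAELKKELFELRFQAAAGRLENTAKLDEVKKTIARVKTVQRELTK*	7943.3
Lactococcus sp002492185	30S ribosomal protein S20	MANIKSAIKRAELNVAANERNSQQKSAMRTAIKKFEKAPSEDTYKAASSAIDKAASKGLIHANKASRDKSRLAAKLG*	8128.3
Lactococcus sp002492185	30S ribosomal protein S18	MAFQKRGGFKRRKKVDFIAANKIEVVDYKDTELLKRFISERGKILPRRVTGTSAKNQRKVVTAIKRARVMALLPFVASDEN*	9177.8
Lactococcus sp002492185	30S ribosomal protein S17	MERNQRKVYQGRVVSDKMDKTITVVVETKRNHPVYGKRINYSKKYKAHDENNTAKTGDIVRIMETRPLSKDKRFRLIEIVEEAVII*	10177.8
Lactococcus sp002492185	30S ribosomal protein S16	MSVKIRLTRMGSKKKPYYRINVADSRSPRDGRFIETVGTYNPLVAENQVTLKEERVMEWLNNGAQPSDTVRNILSKAGIMKKFHEQKYSK*	10301.9
Lactococcus sp002492185	30S ribosomal protein S15	MAISKEKKQEIIKQYARTEGDTGSPEVQIAVLTWEINHLNDHIKAHKKDHATYRGLMKKIGHRRNLLAYLRKKDVQRYRELIASLGLRR*	10347.0
Lactococcus sp002492185	30S ribosomal protein S19	MSRSLKKGPFADEHLMKKVEAQENAEKKSVIKTWSRRSTIYPNFVGLTIAVYDGRKHVPVYVQEDMVGHKLGEFAPTRTYRGHAADDKKTRR*	10460.0
Lactococcus sp002492185	50S ribosomal protein L24	MFVKTGDTVKVIAGKDRGTTGKVIKALPKVNKVIVEGVAIVKKHQKPDAVNPNGAILEIEAPIHVSNVQVLDKNGVAGRVGYKEVDGKKVRFNKKSGEVLD*	10799.7
Lactococcus sp002492185	50S ribosomal protein L23	MSLYDVIRKPIITEASMQAMDQKKYTFEVDARAHKLLIKQAVEAAFEGVQVASVNTISVKPKAKRVGRYTGFKPGYKKAIVTLTEGSKSIDLFGEGEDAE*	10909.6
Lactococcus sp002492185	30S ribosomal protein S10	MATKKIRIRLKAYEHRILDAAAEKIVETAKRTNAEVSGPIPLPTDRSVYTVIRATHKYKDSREQFEMRTHKRLIDIIEPTQKTVDSLMKLDLPSGVNIEIKL*	11611.5
Lactococcus sp002492185	50S ribosomal protein L22	MAEITSAKATARTVRVSPRKTRLATDLIRGKRVADAIAILKFTPTKGAAEVLKVMNSAIANAENNFGLEKANLVVSETFVNEGPTMKRFRPRAKGSASPINKRTSHITVVVAEKE*	12303.3
Lactococcus sp002492185	50S ribosomal protein L18	MISKPDKNKLRQKRHIRVRGKISGTAETPRLNVFRSNTNIYAQVIDDEAAVTLASASSLKLTGTKTEQAAEVGKLIAEAAKAKGIEAVVFDRGGYLYHGRVQALAEAAREAGLKF*	12454.3
Lactococcus sp002492185	50S ribosomal protein L19	MSISLIDSINAGQLRSDIPEFRPGDTVRVHAKVVEGTRERIQMFEGVVIARKGSGISETYTVRKISNGVGVERIFPLHTPRVEKIEVIRHGRVRRAKLYYLRALQGKAARIPERRK*	13060.2
Lactococcus sp002492185	30S ribosomal protein S11	MAKITRKRRVKKNIETGIAHIQSTFNNTIIMITDVHGNALAWSSAGSLGFKGSKKSTPFAAQMASEAAAKAAQEQGLKTVSVTVKGPGSGRESAIRALAAAGLNVTSISDVTPVPHNGARPPKRRRV*	13173.1
Lactococcus sp002492185	30S ribosomal protein S13	MARFAGVDIPNEKRIVISLTYVYGVGLQTAKKVLAAAGVSEDVRTKDLTSDQEDAIRRELDGLKLEGDLRREVNLNIKRLMEIGSYRGMRHRRGLPTRGQNTKNNARTRKGPAKAIAGKKK*	13358.4
Lactococcus sp002492185	30S ribosomal protein S9	MAQVQYAGTGRRKNSVARVRLVPGTGKIVINKRDVEDYIPQAALRLVINQPFAATQTEGSYDTLVNVNGGGVSGQSGAIRHGIARALLEVDPDFRGALKRAGLLTRDARMVERKKAGLKKARKASQFSKR*	13971.1
Lactococcus sp002492185	30S ribosomal protein S12	MPTINQLVRKGRHSKVEKSNSPALNIGYNSRKKLQTKVASPQKRGVATRVGTMTPKKPNSALRKFARVRLSNLIEVTAYIPGIGHNLQEHSVVLLRGGRVKDLPGVRYHIVRGALDTAGVTDRKQSRSKYGTKKPKA*	15002.5
Lactococcus sp002492185	50S ribosomal protein L15	MKLHEMKAAEGSRKVRNRVGRGTSSGNGKTSGRGQKGQKSRSGGGVRPGFEGGQTELFRRLPKRGFTNVNRKEYAIVNLDTLNRLGDGAEVTAETLVAAKIIKDVKSGIKVLANGELTVKNLKVNVAKASAAAKAAIEAAGGSVETLEAK*	15718.0
Ligilactobacillus murinus	50S ribosomal protein L34	MKRTYQPKKRHRQRVHGFRKRMSTSNGRNVLARRRRKGRKVLSA*	5391.4
Ligilactobacillus murinus	50S ribosomal protein L30	MANLKVTLVRSVIGRPQNQREIVKGLGLGRVNSSVVVPDNAAMRGAIRKINHLVDVELAK*	6372.5
Ligilactobacillus murinus	50S ribosomal protein L28	MAKDFVTGRKTTFGKKRSHALNQTNRSWKPNLQKVRILVDGKPKKVWVSARALKSGKVTRV*	6819.0
Ligilactobacillus murinus	50S ribosomal protein L35	MPKQKTHRASAKRFKRTGNGGLKRAHAFTSHRFHGKTKKQRRQLRKPAMVSASDMKRIKQMLSQMK*	7588.0
Ligilactobacillus murinus	50S ribosomal protein L29	MKINEINELTTAEMLEKEKQFKEELFNLRFQLATGQLENTARLKEVRKTIARIKTALRQQELNK*	7620.9
Ligilactobacillus murinus	50S ribosomal protein L24	MFIKSNDKVKVIAGKDKGKEGVVIKAFPANDRVIVKGVNIVKKHQKPNNANPNGGIVEMEAPIHVSNVKKISE*	7918.3
Ligilactobacillus murinus	30S ribosomal protein S18	MPQQRRGGRRRRKVDFIAANHIEYIDYKDTDLLKRFISERGKILPRRVTGTSAKNQRKLTVAIKRARIMGLLPFVAED*	9007.5
Ligilactobacillus murinus	30S ribosomal protein S20	MPIIKSAIERVKTNEKANARNSAELSKMRTAIKKFEKAKTAGAEDVEKLYREAVSAVDRAHSKGLIKANKAARDKSRMAARLAK*	9138.6
Ligilactobacillus murinus	50S ribosomal protein L31 type B	MKQGIHPDYHKVVFMDSATGYKFLSGSTKTTEETIEWEDGNTYPLIRVEISSDSHPFYTGKQKFTQADGRVDRFNKKYGFTN*	9475.5
Ligilactobacillus murinus	30S ribosomal protein S17	MSEGRNQRKVYQGRVVSDKMEKTITVVVETYVNDKVYGKRVKYSKKYKAHDENNEAKVGDIVKIMETRPLSATKRFRLLEIVEKAVII*	10117.8
Ligilactobacillus murinus	30S ribosomal protein S15	MAISNEKKNEIMKKYARHEGDTGSAEVQIAVLTADINELNEHVRSHKKDFASQRGLMKKIGHRRNLLAYLRNKDVQRYRELIKSLGLRR*	10257.8
Ligilactobacillus murinus	30S ribosomal protein S16	MSVKIRLKRMGSKKRPFYRIVVADSRSPRDGRFIETVGTYNPLTQPEQVTLKEEAIMGWLNNGAQPSDTVRNILSKEGVMKKFHEAKYSKK*	10340.0
Ligilactobacillus murinus	30S ribosomal protein S19	MSRSLKKGPFVDEHLMKKVEAQADQEKKSVIKTWSRRSTIFPSFIGYTIAVYDGRKHVPVYIQEDMVGHKLGEFVPTRTFHGHAADDKKTGKK*	10517.1
Ligilactobacillus murinus	50S ribosomal protein L23	MESRDVILRPIITEASMNEMDNKRYTFEVDLRANKTQVKDAVEDIFEVEVAKVNIMNVKGKKKRMGRYEGYTRKRRKAIVTLKPESKDIQLFNEE*	11226.0
Ligilactobacillus murinus	30S ribosomal protein S10	MAKQKIRIRLKAYEHRILDQSADKIVETAKRTGAQISGPIPLPTERTIYTVIRSPHKYKDSREQFEMRTHKRLIDIVNPTPKTVDSLMKLDLPSGVDIEIKL*	11648.6
Ligilactobacillus murinus	50S ribosomal protein L7/L12	MALDTEKIIADLKEASILELNDLVKAIEEEFGVSAAAPVAAAGAAAGAAEEKSEFDVELTDPGAGKVKVIKAVKDITGLGLKDAKGLVDGAPSVIKEGVAKEEAEEIQAKLEEVGAKVTLK*	12240.0
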