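>ASCa-1
FLRMHTFFDSGANNHSSTRRLWCNMSAQSLVHVEENKLMGMVFPEARNLGLHDNSLGRHV
>ASCa-2
FLRMHTFRDSGANNHSDTRRLWCNNLAQSLKHKEENELMGQVFPESRNLGLHDNSLGRGV
>ASCa-3
FLRMHDFRDSGANNHSITRRLWCNMSAQSLVHVEENNLMGQVFPEARNLGLHDNSLGRHV
>ASCa-4
FLRMHTFRDKGANNASITRRHWCNMSAQSLVHVEENNLMGQVFPEARNLGLHDNSLGRHV
>ASCb
VLYKHTEYDNGMNNHSITQRIECNAFAQLGHHCSENNLMGQVFVELSELGLKMNSLGRHV
>MyoD
NLRMHTARDEGTNKASQAQRLVCNPSAQSNHHCEENNIMGQVFPEAFELLLAPNCDGRHV
>Da
KLKMHTRDDEGTNAHSIVERIPCNDSAQSLHHVLEFQLMMQVFPEARELLLAGNSLGKHV
>Ngn
LLRMHTGDDMSTNNLSRKQRLECNVSCQSFNHEEENNSMAHVDPEAFYLTLASNSLGRHV
>NeuroD
FLRMHVFRDEGTNNHSITGRCECNKSNQISHHCQECFSMGTVLPEAVSLALAANSLGGHV
>Atonal-1
NLRMHAFRDEGTNFHSSTQRFECNVIVQRMHHVEEANLMRQVRPEGFLLGLRTNSRGHHV
>Atonal-2
FLMMHAFRDCGTNKHSSTQRFECNVIVQRLHHVEEENLMSQVRPEGFLLGLIQNSGGHHV
>Atonal-3
FLRMHAFRDEGTNLLSSTQRFECNVIVQALHHVEEANLMSQVQPEGFLLGLRTNSGGHHV
>Mist
KLPMHTFTDEYTNNHSTTQRLECNVSKQSLHHCEESCLMPQVGPEAFELPLAANSLGRHV
>Beta3
GLRVHFFLDEGTNQLSIEYRLECNVSDQAEHHCVEYNEMYQVFPEMDELGLIKNPEGWHV
>Oligo
FLVVHTFYDEQANNHSQTQRLLCNKLAQSDHHQTESYLMGQVFWESKELLLAENSKGRPV
>Net
LLRMHSFMDAETNNHSPTQRLMCNRSAQSLHHYEENKLMILVFDEAFELVLTVNELGRLV
>Mesp
FLVMHTRQDEVTNHHSIPQRRECNVSAQGLHHCEESNEMIQVTPEPFLLGLQPNSRGVHV
>Twist
FLRMHTFRDVGRNAESITARKLCNGIAQSSPHGEENNLMGQVFPEAFELGLANNGIGRHV
>Paraxis
FLSAHCFEDEGINNYSIMQRLECNVSAQTILHCTEEFAMIQVIFEFGGLKLARNSLGRHV
>MyoRa
FLASHTFRDEATNNNSITQRNECNVAIQALHHCEEKNLMSQVFPEAVELTLEENLFGQTV
>MyoRb
FLRIHTFYDELTNNHSITQRLECNVSAQSLHHTEEGSEMSQVQPEAFALDLLKNSLGRHV
>Delilah
FLRGHTKRDQKHNNHSINRRLECNVKAQFLHHCEEENRMTQVFPEALELDLAANHCGRHV
>Hand
FLRMHTFRDEGTNNHSLWQRLECNVSAQSHHHLEEQNLMGQVHNEAFELILAQNSLGNHV
>PTFa-1
FLRMHLDRDEGTNNGSIPQRLECNESAQDHHHCEECNCMCVVFPEGALLGLAANTLGRHV
>PTFa-2
FLRMHTDRDMGLNNGSIPQRLECNESAQSHHHCEECNCMCVVFPEGALLGLAANTLGRAV
>PTFb
FLCMHETTDEGFNNISITQRLECNVKGQSLHHCEENNTMGRVFPEAFELKLAANSDGAHV
>SCL
VLRTHTVRDEGTNLHSILCRLLCNVSAQIPQHCEENGAMNQVSPEAGELALLANSLGRCV
>NSCL
FLRLHTFGDEGPNNNSTTNRRECNVRAQSLHHTEENVLMLQVTIEAFCLKLDDNTLGTHV
>Myc-1
SLRSHTGRDQGTNSHSMRQRLECNMSSQILHHCEENNLMGQVFWEAKELKLGANAHGGHV
>Myc-2
SLRAHDARDQGTNNHSMRQRLECNVSSQILHHCGEGNPMGQVFWEAAELKLGANAHGGVV
>Mad
FLGMHTFPDESENNHSATTRSNCNAGAQSHHHLEEVLLMGRVFPEACGLGLEANVGGRLV
>Mnt
FLFAHDERDEGTNNHSHIQRLECNHKAQSLHHCEENNLMGRVFMEAFLLPLATNVLGRKV
>Max
RLKFHPFRDEGVNNHSITQRSECNVMAQSMVHHTENNQMGLVFPEACELGLAANSSGFPV
>USF
GLRMHHFRDEAINECSIRQRKECNGSIQDAHHGLEINWMGTVFEEAFELVLAANRVGRHV
>SREBP
FLLVHSFCDEGNNQHSITDRLECNISAQSWHHCEEPFLMGQVAEEAQKLGLPANTPGGHV
>MITF
FLKDHTFRDEGPNAQSIKQRLECNEQIQSNHHFEENRLMGYVNEEAFVLGLAANIHGIHV
>TF4
FLRQHTFRDETTNDHSIQGRQECNVSAQSLPHQEENNDMLGVSPEAFELGLAQNVLGRAV
>MLX
NLAEHDFADELTNNHSITIRTKCNVAIQPGHHREEETLMGQVFPEAFCLKLALNSAGRDV
>AP4
QLRMHTFEDELRNIHSITKRLECNVSEQVRHHCEEENFMGAVFPEAFELPLAANSLGLMV
>Bmx
ALRMHTFRDEGTNNHSITQRFLCNLTSQSLHHCEENQLMGQVFREAPLLWLPANSLGRHV
>Figalpha
ELRMHFFRDEGTNNCSSTYRLECNVSAQSLHHCYEGTEMLQVDSEAFTLGLQANSLGSHV
>Clock
FLRAHVFLDEAANNHSNTQRLGCNVSLQSEYHCNEVNLMQAVATEVFELGLAPNSLGRHV
>Cycle
FLRMHTDLDDKTNNRSYRQRSECNVSAQSRGHCEEPNNMRQVNPEAFELGLAANKVGRHV
>ARNT
FLSMHIFRDEGLNSHSITQRLICNWSAQSDLHCEENRLMGQVFNEAMDLGLAANSYGRHV
>Sim
ILPMHTFLDEETNNHSITFRLECNVSAQPAHHCEENNAMGVVFPEAFELPLAANDLGRTV
>Trh
FLEMHLFRDEPTNELSKRARRPCNVSAQKLHHCEENNLMGEVYPEAFELGLLANSLGHHV
>HIF
FLEMHTFTDEGLNNSSLWQRLQCNSVKQSLHHCEELNLMLQVFPEAFELGLAANDLGRHV
>AHR
FLGMHTFRDERENQHSTTVRIGCNQPAQQLKHASENLLMGQVVCEAFELKLADNSFGRHV
>Emc
CLWMHTPRDEGSNNGSIPQRLECNVSPQELKHCPELELMEQVFPEADELLLPKNHLGRHV
>HES-1
FLRGHIVRDDAGNNHSITQRLECNVPAQELHHEEENALMGLVFEEAKELGLAANDLGRHV
>HES-2
FLRGHIVRDEAGNNHSITQRLECNVSAQEENHEEENFLMGKVFEEAKELGLAANRLGRHV
>HES-3
FLRGHIVRDEAGNNHSIMQRSECNVSAQELHHEEEVFLMGLVFEEAKELKLAANRLGRHV
>HES-4
FLRGHIVRDEAGNSHSITQRLNCNVSAQELHHEEENNLMGLVFEEAKELGLAANRLGRHV
>HES-5
FLRGHIVRDEAGNNNSITQRLECNVSAQEIHHKEENNLMGLVFEEAKELGLAVNRRGRHV
>HES-6
FLNGHIVRDEAGNNHSIECRLECNVSAQELHHEEENNLMGLVFEEAKELGLAANRLGRHV
>HES-7
FLRGHIVRDEAGNNHSITQRLYCNVSAQELYHEEENNLMGLVFEEATELGLAANRLGRHV
>HES-8
FLRGHVVEDEAGNNHSITQRLECNVSAQELHHEEENVLMGLVFEELKPLGLAANRLGYHV
>Hey
DLAMHTTRDEGTNNHSITTRLECNFSGQSLGHCEEVNLMTQVWAEACELGLAANRLGYVV
>Kn
ILVMHTRRDEPTNHKSITLRLECNVPLQSLHHCQENNLMGTVFKEHFILQLQANQLGLCV
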