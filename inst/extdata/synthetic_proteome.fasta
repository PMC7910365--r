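>SYNF001 OS=Triticum aestivum
MERNSSPGKSKSLLLRDSVEAVATLNNVPSGAISGIEESDFSTTLVSFGDDVWFYGRAEM
PKLPHCDWTTGPRPKRLSLQWDQSSLGTAINLQELSGALRQCFTDKVVSRAVAHTYVCSS
YNCTVKTGVDVPRFQTIQTNALAQRATVLNSNDTARFGKSKDPLVGVVVDTARDGAPQLG
TNRDETWLLKLRVSMNVSSWSTHQKRTGPITIPNDVHPPRDLSLKLIAGVATFLGVDFSM
DGVRWRRERDDNQGVFTNRELEFTKQNLGGATDWERNKRGDGENPTHYFPAREEMYAEKE
PPSS
>SYNF002 OS=Hordeum vulgare
MLVALLCARHAHDSPTRMHGRPGGSWAENTLKGGGRAKAGVKVDICNDIIFLDPQPGRAE
NQLRVRDREVPQRERLEGSPACAYTPLMFMSFLYHPTELVESTGLKLVEASAYSRHNAIQ
VANEDTHTANRIPKSCETTPTTIAKSPLIFPDITVSRERKEVTPKAAATYQMKGLRRITL
TNEGSELQRLNQQQLHWTTEDSRNL
>SYNF003 OS=Bos taurus
MTTRSVMRVGALERIAVSSKFDIYAVKYNWQPIVVVVTQLSSLSVSGNAGPYYNLMYIYM
IHYEMLLRQEAFDNHVSSGATRAMLTAELITVYETDRAPAGFPGTLAHNSPGNPLKAVSL
MVVIQIILDYLVPGMNGSLEWPEVVVSFINSELEGRTSKIHWGIITQEGIGPAVPDYLSS
DYIDVILLIELIWYATASVNGQVGQILSPANVGCYPGIVSKIL
>SYNF004 OS=Ovis aries
MFIKGTPLPAYGTQPTVFYNALKADTILGNGKRSTNMERFTRVWQSYNIAGKLAFLDWYP
SDAEEYSLFESLYEAIPNRTKDSVLAQYAKLVSLHLAASALILKNTPLFWSMLVLRDALV
SCRAARYPAHLDITRNYNVTGGPVTALTYGIGERCLNQSKLSVEPIAHFHNDKWS
>SYNC001 OS=Homo sapiens
MRHGLEITAFFKAAWAYGLTITHQEEKSDTGGKFQTDAEQMRTMKGVPESPSIRYTTALR
RASTHLILQEKYYNFIGSSEADLFDNDMAGAVADYHEIRKQGAREKRKPEAAKAFGSDID
ARKPQVAVADNTPDSSDNKKSRSVPVSPDTSSDIVKSLIRYPKLDPRACRFIARTTDKRY
SPLGISTLEFWSEYSLKNEVFVDGDDSIAESESTVPGLRDVEVGPAIQQ
>SYNC002 OS=Homo sapiens
MGIVSENAIFGRGEVIPMVILTCAFGGKRTKLSILPGYYKGRESHWPVHSIKRWEQGTTQ
FNRWPARIIPYDQIEWCDSPAQHTFLSNVQVYKGVKISEILGLSADPLVCVPFYRKSDQD
VPHGITDLAEPFTFKLLTEDVLLVKTHSGGAILVRLSYNSIREYLPGGTSGVGLLELPIA
IRNAIVEAPQYSDKPTTSYMDIAGDYSDAILVPFSLSFRRWRYPTSQSKAALGPIKAFQV
NSKYLPLTAGNLLLETQEESSSSLVMRLSVHSTMRLKVS
>SYNC003 OS=Homo sapiens
MVIKNYLAHMVTLQLMIPVTSVGLSGFPILFDGDIESTPDILDEHLVATKLAVEPMQRSG
QQPTEEASTVPIDKNRPQDVNPSEALLGMWISDGDEKPILEQIARVIDIGPRTNNYALAL
PTLDLWNIILGGVALLRACLNFHNPPKTYARPSTAQQLHVHYVYEHTVNKAGASVSLGSH
GLGYDPTVTNKSVSPI
>SYNC004 OS=Homo sapiens
MAVQKYDLDKCEDFIHHGKEAKKDVAAWSTSKNKVAVFATELTVHDLSASLTEAPYLPAM
EEEAHKIRKIESHPFLWSNYDSYKKNNAGKHILSLQHSFAYQKPDQTDLHAKFLQSQSES
YTQIKGYENAAIGGTDIGSRKNLLRMNVFQPSQTAVSIFYGAILGQGQTIRRGASMDYPD
DEQIVNIFEAYSPGHWLAQKLGTFAILQMPGRKLAGLDASIVITPNTQCHKLIIRLSGDK
PLFQNLGCFWPLAWDQEDA
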