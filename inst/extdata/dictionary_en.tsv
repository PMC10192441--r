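code	phrase
LLL	Water
LLR	Adjust my Specs
LLU	Feeling Cold
LLB	Feeling Hot
LRL	Emergency
LRR	Nose Block
LRU	Palpitations
LRB	I am not Okay
LUL	Choking
LUR	Heartache
LUU	Danger
LUB	Dizziness
LBL	Headache
LBR	Breathless
LBU	Cramps
LBB	Let's Talk
RLL	I Want to Go Home
RLR	Wipe
RLU	Wash
RLB	Scratch
RRL	Change Clothes
RRR	Food
RRU	Change Position Sitting
RRB	Change Position Lay straight
RUL	Let's Go Out in the Open
RUR	Open the Door
RUU	Open the Window
RUB	Television
RBL	Music
RBR	Light
RBU	Air Conditioning
RBB	Newspaper
ULL	Comb my hair
ULR	I Want to Spit
ULU	Change Bedsheet or Pillow
ULB	Someone is hurting me
URL	Call a Doctor
URR	Take a Shower
URU	Food Stuck in Teeth
URB	I Need a Hug
UUL	Call the Police
UUR	Call a Relative
UUU	Toilet
UUB	Change Diaper
UBL	My Phone Camera is not Working
UBR	My Computer is not Working
UBU	Good to See You
UBB	My Wheelchair is not Working
BLL	No
BLR	Hello
BLU	Long time no see
BLB	I Want to Sleep
BRL	I Want to meet my Pet
BRR	Yes
BRU	I Want to Pray
BRB	The Internet is not Working
BUL	Congratulation
BUR	I am sorry
BUU	I love you
BUB	How are you
BBL	I am in Pain
BBR	Medication
BBU	Thank You
BBB	I am Okay
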